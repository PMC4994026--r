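#' Prior specification for model inversion
#'
#' All free parameters are log-scaling deviations with prior mean 0 (i.e.
#' physical value = default * exp(theta)); each belongs to exactly one class
#' with a class-level prior variance.  Tighter priors are placed on
#' biophysical constants (gain, delays, time constants) than on the
#' connectivity parameters of interest.
#'
#' @param variance named numeric of prior variances per parameter class:
#'   `A` extrinsic strengths, `B` condition modulations, `C` input gains,
#'   `G` superficial-pyramidal gain, `D` conduction delays, `T` synaptic time
#'   constants, `L` observation gains.
#' @param mean prior expectation of every log-scaling parameter (scalar).
#' @param hyper_mean,hyper_var Gaussian hyperprior on the log noise precision.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(variance = c(A = 1 / 8, B = 1 / 8, C = 1 / 8,
                                    G = 1 / 16, D = 1 / 16, T = 1 / 32,
                                    L = 1 / 8),
                       mean = 0, hyper_mean = 4, hyper_var = 1) {
  need <- c("A", "B", "C", "G", "D", "T", "L")
  if (!all(need %in% names(variance))) stop("variance must cover all classes")
  if (any(variance <= 0) || hyper_var <= 0) stop("variances must be > 0")
  structure(list(variance = variance[need], mean = mean,
                 hyper_mean = hyper_mean, hyper_var = hyper_var),
            class = "prior_spec")
}

# ordered edge list of a strength matrix as linear indices + labels
.edge_ix <- function(m) {
  idx <- which(m != 0)
  rc <- arrayInd(idx, dim(m))
  list(lin = idx,
       label = paste0(colnames(m)[rc[, 2]], "->", rownames(m)[rc[, 1]]))
}

#' Pack model parameters into a flat log-scaling vector
#'
#' Builds the bijective map between named free parameters and vector
#' positions used by [variational_laplace()].  Classes: `A` — one parameter
#' per extrinsic component (forward onto ss/dp, backward onto sp/ii); `C` —
#' input gains of declared input sources; `B` — one condition modulation per
#' extrinsic edge (tied across the edge's two components) plus one per-source
#' gain modulation; `G` — per-source superficial-pyramidal gain; `D` — one
#' delay per extrinsic edge plus a per-source self delay; `T` — four synaptic
#' time constants shared across sources; `L` — per-source observation gain.
#' Physical value = default * exp(theta) for every positive-constrained
#' parameter; `B` is itself a log-scaling deviation (repeated = novel *
#' exp(B)).
#'
#' @param model a `dcm_network`.
#' @param mod optional [condition_modulation()] providing starting values for
#'   the `B` parameters (per-component values are averaged within an edge).
#' @param obs an [observation_spec()].
#' @param params a [cmc_parameters()] shared by all sources.
#' @return object of class `dcm_parameterization` with `names`, `classes`,
#'   `theta0`, and internal index tables used by the predictor.
#' @export
pack_parameters <- function(model, mod = NULL, obs = observation_spec(),
                            params = cmc_parameters()) {
  stopifnot(inherits(model, "dcm_network"))
  nm <- model$sources$name
  n <- length(nm)
  fe <- .edge_ix(model$A_forward$ss)   # forward support (ss component)
  fe2 <- .edge_ix(model$A_forward$dp)
  be <- .edge_ix(model$A_backward$sp)
  be2 <- .edge_ix(model$A_backward$ii)
  if (!identical(fe$lin, fe2$lin) || !identical(be$lin, be2$lin))
    stop("forward (or backward) component supports differ")
  cin <- which(model$C > 0)

  blocks <- list(
    list(names = paste0("A.fss.", fe$label), class = "A"),
    list(names = paste0("A.fdp.", fe$label), class = "A"),
    list(names = paste0("A.bsp.", be$label), class = "A"),
    list(names = paste0("A.bii.", be$label), class = "A"),
    list(names = paste0("C.", nm[cin]), class = "C"),
    list(names = paste0("B.", fe$label), class = "B"),
    list(names = paste0("B.", be$label), class = "B"),
    list(names = paste0("B.G.", nm), class = "B"),
    list(names = paste0("G.", nm), class = "G"),
    list(names = paste0("D.", fe$label), class = "D"),
    list(names = paste0("D.", be$label), class = "D"),
    list(names = paste0("D.self.", nm), class = "D"),
    list(names = paste0("T.", cmc_populations), class = "T"),
    list(names = paste0("L.", nm), class = "L")
  )
  names_all <- unlist(lapply(blocks, `[[`, "names"))
  classes <- rep(unlist(lapply(blocks, `[[`, "class")),
                 vapply(blocks, function(b) length(b$names), integer(1)))
  if (anyDuplicated(names_all)) stop("parameter name collision")
  p <- length(names_all)
  pos <- split(seq_len(p), factor(classes, levels = c("A", "C", "B", "G",
                                                      "D", "T", "L")))

  theta0 <- stats::setNames(numeric(p), names_all)
  if (!is.null(mod) && length(mod$b)) {
    stopifnot(inherits(mod, "condition_modulation"))
    # average per-component b within each edge; map gain modulations directly
    for (lbl in unique(c(fe$label, be$label))) {
      comp <- paste0("A.", c("fss", "fdp", "bsp", "bii"), ".", lbl)
      hit <- intersect(names(mod$b), comp)
      if (length(hit)) theta0[paste0("B.", lbl)] <- mean(mod$b[hit])
    }
    gh <- grep("^G\\.", names(mod$b), value = TRUE)
    if (length(gh)) theta0[paste0("B.", gh)] <- mod$b[gh]
  }

  structure(list(
    model = model, obs = obs, params = params,
    names = names_all, classes = classes, n_par = p, theta0 = theta0,
    ix = list(fwd = fe, bwd = be, cin = cin,
              nf = length(fe$lin), nb = length(be$lin), n = n,
              pos = pos),
    contribution = obs$contribution,
    gain0 = rep_len(obs$channel_gain, n)
  ), class = "dcm_parameterization")
}

# split a packed theta into per-block pieces, in pack order
.theta_blocks <- function(pack, theta) {
  ix <- pack$ix
  nf <- ix$nf; nb <- ix$nb; n <- ix$n; nc <- length(ix$cin)
  sizes <- c(fss = nf, fdp = nf, bsp = nb, bii = nb, C = nc,
             Bf = nf, Bb = nb, BG = n, G = n,
             Df = nf, Db = nb, Ds = n, T = 4, L = n)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  out <- lapply(seq_along(sizes), function(i)
    if (sizes[i]) theta[starts[i]:ends[i]] else numeric(0))
  names(out) <- names(sizes)
  out
}

#' Effective physical parameters for a packed vector
#'
#' Expands a log-scaling vector into the physical-scale quantities used by
#' the integrator, per condition.
#'
#' @param pack a [pack_parameters()] object.
#' @param theta numeric vector of length `pack$n_par`.
#' @return list with `novel` and `repeated` effective models (strength
#'   matrices, `C`, `D`, `G`), plus `tau`, `gain` (observation), `b` (per-edge
#'   modulations).
#' @export
unpack_parameters <- function(pack, theta) {
  stopifnot(length(theta) == pack$n_par)
  tb <- .theta_blocks(pack, theta)
  ix <- pack$ix
  m <- pack$model

  eff <- function(repeated) {
    Afss <- m$A_forward$ss; Afdp <- m$A_forward$dp
    Absp <- m$A_backward$sp; Abii <- m$A_backward$ii
    bf <- if (repeated) tb$Bf else 0
    bb <- if (repeated) tb$Bb else 0
    Afss[ix$fwd$lin] <- Afss[ix$fwd$lin] * exp(tb$fss + bf)
    Afdp[ix$fwd$lin] <- Afdp[ix$fwd$lin] * exp(tb$fdp + bf)
    Absp[ix$bwd$lin] <- Absp[ix$bwd$lin] * exp(tb$bsp + bb)
    Abii[ix$bwd$lin] <- Abii[ix$bwd$lin] * exp(tb$bii + bb)
    C <- m$C
    C[ix$cin] <- C[ix$cin] * exp(tb$C)
    D <- m$D
    D[ix$fwd$lin] <- D[ix$fwd$lin] * exp(tb$Df)
    D[ix$bwd$lin] <- D[ix$bwd$lin] * exp(tb$Db)
    G <- m$G * exp(tb$G + if (repeated) tb$BG else 0)
    list(Afss = Afss, Afdp = Afdp, Absp = Absp, Abii = Abii, C = C,
         D = D, D_self = m$D_self * exp(tb$Ds), G = G)
  }

  list(novel = eff(FALSE), repeated = eff(TRUE),
       tau = pack$params$tau * exp(tb$T),
       gain = pack$gain0 * exp(tb$L),
       b = list(edges = c(tb$Bf, tb$Bb), gain = tb$BG))
}

#' Build a fast two-condition predictor
#'
#' Returns `function(theta)` producing the predicted ERP stack
#' `[n_sources x 2 n_times]` (novel columns then repeated columns) for a
#' packed parameter vector.  Used by [variational_laplace()] and by the
#' synthetic-data generator, so fitted and generated data share one forward
#' model.
#'
#' @param pack a [pack_parameters()] object.
#' @param input a [stimulus_input()].
#' @param grid a [simulation_grid()].
#' @param v_bound instability bound passed to the integrator.
#' @return function of `theta`.
#' @export
make_predictor <- function(pack, input = stimulus_input(),
                           grid = simulation_grid(), v_bound = 1e3) {
  n <- pack$ix$n
  prm <- pack$params
  gmat <- matrix(prm$g, 10, n)
  slope <- prm$sigmoid_slope
  ext <- prm$ext_gain
  w <- pack$contribution
  gsp0 <- prm$gain_sp
  src_names <- pack$model$sources$name
  nt <- length(grid$times)
  t0 <- min(0, grid$t_start)

  sim_one <- function(e, tau, gain) {
    res <- .cmc_integrate_cpp(
      n, gmat, matrix(tau, 4, n), slope, gsp0 * e$G,
      e$Afss * ext[["f_ss"]], e$Afdp * ext[["f_dp"]],
      e$Absp * ext[["b_sp"]], e$Abii * ext[["b_ii"]],
      e$D, e$D_self, e$C,
      input$onset, input$dispersion, input$amplitude,
      t0, grid$t_end, grid$dt, v_bound, grid$times)
    if (isTRUE(res$diverged))
      stop(sprintf("network integration diverged at source '%s' (t = %.1f ms)",
                   src_names[res$source], res$time))
    # project population voltages to the source signal
    m <- matrix(res$v, nrow = 4)           # 4 x (n * nt), population fastest
    e_sig <- matrix(crossprod(w, m), n, nt) * gain
    rownames(e_sig) <- src_names
    e_sig
  }

  function(theta) {
    u <- unpack_parameters(pack, theta)
    cbind(sim_one(u$novel, u$tau, u$gain),
          sim_one(u$repeated, u$tau, u$gain))
  }
}

.prior_vectors <- function(pack, priors) {
  v <- unname(priors$variance[pack$classes])
  list(mean = rep(priors$mean, pack$n_par), var = v)
}

#' Invert a network model with variational Laplace
#'
#' Gauss-Newton / Levenberg-Marquardt ascent on the variational free energy
#' `F = accuracy - complexity` under Gaussian priors on log-scaling
#' parameters and a single log noise-precision hyperparameter with a Gaussian
#' hyperprior.  The Jacobian of the forward prediction is obtained by central
#' finite differences.  Steps are accepted only if they increase F, so the
#' accepted-step F sequence is non-decreasing by construction; rejected steps
#' raise the Levenberg damping.  Convergence is declared when the F gain stays
#' below `tol` for `tol_consec` consecutive accepted iterations.
#'
#' @param data an [erp_dataset()] on the same grid as `grid`.
#' @param model a `dcm_network`.
#' @param priors a [prior_spec()].
#' @param init optional starting means (named like the packed vector, e.g.
#'   from [reinitialize_low_fit()]).
#' @param obs,params,input,grid forward-model pieces (see
#'   [pack_parameters()], [make_predictor()]).
#' @param control list overriding `max_iter` (64), `tol` (0.01 nats),
#'   `tol_consec` (4), `fd_step` (1e-3), `max_reject` (6), `v_bound` (1e3).
#' @return object of class `dcm_posterior`: `Ep` (posterior means, log-scaling
#'   domain), `Cp` (posterior covariance), `F` (free energy, nats), `fit`
#'   (variance explained), `lambda` (posterior log precision), `n_iter`,
#'   `F_trace` (accepted-step free energies), `classes`, `prediction`.
#' @export
variational_laplace <- function(data, model, priors = prior_spec(),
                                init = NULL,
                                obs = observation_spec(),
                                params = cmc_parameters(),
                                input = stimulus_input(),
                                grid = simulation_grid(),
                                control = list()) {
  stopifnot(inherits(data, "erp_dataset"))
  ctl <- utils::modifyList(list(max_iter = 64, tol = 0.01, tol_consec = 4,
                                fd_step = 1e-3, max_reject = 6,
                                screen_margin = 0.005, v_bound = 1e3),
                           control)
  if (!isTRUE(all.equal(as.numeric(data$times), as.numeric(grid$times))))
    stop("data grid incompatible with model simulation grid")

  pack <- pack_parameters(model, obs = obs, params = params)
  pred <- make_predictor(pack, input = input, grid = grid,
                         v_bound = ctl$v_bound)
  pv <- .prior_vectors(pack, priors)
  p <- pack$n_par
  Pi0 <- diag(1 / pv$var, p)
  ldPi0 <- sum(log(1 / pv$var))
  y <- cbind(data$novel, data$repeated)
  yv <- as.vector(y)
  N <- length(yv)
  lam0 <- priors$hyper_mean
  hl <- 1 / priors$hyper_var

  theta <- pack$theta0
  if (!is.null(init)) {
    init <- init[pack$names]
    if (any(is.na(init))) stop("init does not cover the packed parameter set")
    theta <- stats::setNames(as.numeric(init), pack$names)
  }

  h <- ctl$fd_step
  jacobian <- function(th) {
    J <- matrix(0, N, p)
    for (i in seq_len(p)) {
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      J[, i] <- (as.vector(pred(tp)) - as.vector(pred(tm))) / (2 * h)
    }
    J
  }

  # free energy of (theta, lambda) given residual e and the Gauss-Newton
  # curvature JtJ at theta; lambda is updated to its conditional mode by a
  # short Newton loop first
  energy <- function(th, e, JtJ) {
    dth <- th - pv$mean
    ee <- sum(e * e)
    lam <- lam0
    trq <- function(lam) {
      H <- exp(lam) * JtJ + Pi0
      R <- tryCatch(chol(H), error = function(err) NULL)
      if (is.null(R)) return(NULL)
      Cp <- chol2inv(R)
      list(H = H, R = R, Cp = Cp, tr = sum(JtJ * Cp))
    }
    q <- trq(lam)
    if (is.null(q)) return(NULL)
    # Newton steps on lambda, clamped: with near-zero residuals the
    # conditional mode runs away, so cap the step and the range
    for (k in 1:8) {
      d1 <- 0.5 * N - 0.5 * exp(lam) * (ee + q$tr) - hl * (lam - lam0)
      d2 <- -0.5 * exp(lam) * (ee + q$tr) - hl
      step <- max(min(-d1 / d2, 4), -4)
      lam <- max(min(lam + step, lam0 + 28), lam0 - 28)
      q <- trq(lam)
      if (is.null(q)) return(NULL)
      if (abs(step) < 1e-4) break
    }
    Plam <- 0.5 * exp(lam) * (ee + q$tr) + hl
    Fv <- -0.5 * exp(lam) * (ee + q$tr) + 0.5 * N * lam - 0.5 * N * log(2 * pi) -
      0.5 * sum(dth * (dth / pv$var)) +
      0.5 * (ldPi0 - 2 * sum(log(diag(q$R)))) -
      0.5 * hl * (lam - lam0)^2 + 0.5 * log(hl) - 0.5 * log(Plam)
    list(F = Fv, lam = lam, H = q$H, Cp = q$Cp)
  }

  g0 <- pred(theta)
  e <- yv - as.vector(g0)
  J <- jacobian(theta)
  JtJ <- crossprod(J)
  st <- energy(theta, e, JtJ)
  if (is.null(st) || !is.finite(st$F)) stop("non-finite free energy at start")

  F_trace <- st$F
  nu <- 1e-2
  consec <- 0
  n_iter <- 0
  gcur <- g0

  for (iter in seq_len(ctl$max_iter)) {
    grad <- exp(st$lam) * crossprod(J, e) - Pi0 %*% (theta - pv$mean)
    accepted <- FALSE
    for (try in seq_len(ctl$max_reject)) {
      Hlm <- st$H + nu * diag(diag(st$H), p)
      dth <- tryCatch(solve(Hlm, grad), error = function(err) NULL)
      if (is.null(dth)) { nu <- nu * 8; next }
      th_new <- theta + as.vector(dth)
      names(th_new) <- pack$names
      ok <- TRUE
      g_new <- tryCatch(pred(th_new), error = function(err) { ok <<- FALSE; NULL })
      if (!ok) { nu <- nu * 8; next }
      e_new <- yv - as.vector(g_new)
      # cheap screen with the current curvature before paying for a fresh
      # Jacobian; acceptance itself is always judged on the fresh one.  The
      # margin (half the convergence tolerance) stops the terminal rejection
      # phase from re-deriving Jacobians for sub-tolerance gains.
      st_scr <- energy(th_new, e_new, JtJ)
      if (is.null(st_scr) || !is.finite(st_scr$F) ||
          st_scr$F < st$F + ctl$screen_margin) {
        nu <- nu * 8
        next
      }
      J_new <- jacobian(th_new)
      JtJ_new <- crossprod(J_new)
      st_new <- energy(th_new, e_new, JtJ_new)
      if (is.null(st_new) || !is.finite(st_new$F) || st_new$F < st$F) {
        nu <- nu * 8
        next
      }
      dF <- st_new$F - st$F
      theta <- th_new; e <- e_new; J <- J_new; JtJ <- JtJ_new
      st <- st_new; gcur <- g_new
      F_trace <- c(F_trace, st$F)
      nu <- max(nu / 4, 1e-8)
      accepted <- TRUE
      consec <- if (dF < ctl$tol) consec + 1 else 0
      break
    }
    n_iter <- iter
    if (!accepted || consec >= ctl$tol_consec) break
  }

  fit <- fit_score(gcur, y)
  Cp <- st$Cp
  dimnames(Cp) <- list(pack$names, pack$names)
  structure(list(Ep = theta, Cp = Cp, F = st$F, fit = fit,
                 lambda = st$lam, n_iter = n_iter, F_trace = F_trace,
                 classes = stats::setNames(pack$classes, pack$names),
                 model_id = model$model_id, subject = data$subject,
                 prediction = gcur),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("dcm_posterior: model %s, F = %.2f, fit = %.3f, %d iterations\n",
              x$model_id, x$F, x$fit, x$n_iter))
  invisible(x)
}

#' Starting means for re-fitting low-fit subjects
#'
#' Subjects whose model fit is at or above the threshold act as donors; each
#' subject below the threshold receives starting means equal to the
#' element-wise mean of the donors' posterior means for this model.  (A fit
#' exactly at the threshold counts as a donor.)
#'
#' @param posteriors list of `dcm_posterior` for one model across subjects.
#' @param threshold fit threshold (default 0.75).
#' @return named list, one element per subject: `NULL` for donors/keepers, a
#'   starting-mean vector for subjects to refit.
#' @export
reinitialize_low_fit <- function(posteriors, threshold = 0.75) {
  fits <- vapply(posteriors, function(p) p$fit, numeric(1))
  donor <- fits >= threshold
  if (!any(donor))
    stop("no subject reaches the fit threshold; re-initialization undefined")
  out <- vector("list", length(posteriors))
  names(out) <- names(posteriors)
  if (all(donor)) return(out)
  ep <- vapply(posteriors[donor], function(p) p$Ep,
               numeric(length(posteriors[[1]]$Ep)))
  mean_ep <- if (is.matrix(ep)) rowMeans(ep) else ep
  names(mean_ep) <- names(posteriors[[1]]$Ep)
  for (i in which(!donor)) out[[i]] <- mean_ep
  out
}

#' Invert one model for a cohort, with low-fit re-initialization
#'
#' Runs [variational_laplace()] per subject, then re-initializes subjects with
#' fit below `threshold` at the donor-mean posterior (see
#' [reinitialize_low_fit()]) and refits them; refits replace the originals.
#'
#' @param datasets list of [erp_dataset()] (one per subject).
#' @param model a `dcm_network`.
#' @param threshold fit threshold for re-initialization (0.75); set to `NULL`
#'   to skip the second pass.
#' @param ... passed to [variational_laplace()].
#' @return list of `dcm_posterior`, one per subject.
#' @export
invert_cohort <- function(datasets, model, threshold = 0.75, ...) {
  posts <- lapply(datasets, variational_laplace, model = model, ...)
  names(posts) <- names(datasets)
  if (is.null(threshold)) return(posts)
  fits <- vapply(posts, function(p) p$fit, numeric(1))
  if (all(fits >= threshold) || !any(fits >= threshold)) return(posts)
  inits <- reinitialize_low_fit(posts, threshold)
  for (i in seq_along(posts)) {
    if (!is.null(inits[[i]]))
      posts[[i]] <- variational_laplace(datasets[[i]], model = model,
                                        init = inits[[i]], ...)
  }
  posts
}
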