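#' Cohort specification for the synthetic-data generator
#'
#' States the generative world the analysis is tested against: two cohorts
#' whose architectures differ.  The younger-like cohort is generated from
#' model 3 (visual input with a direct visual-to-frontal feedforward edge)
#' with a repetition effect on the anterior ventral temporal
#' superficial-pyramidal gain; the older-like cohort from model 2 (dual
#' visual + frontal input) with repetition effects on the forward connection
#' from early visual to anterior ventral temporal cortex, longer forward
#' conduction delays, and reaction times negatively coupled to frontal input
#' strength.
#'
#' Generative effect sizes default to the printed group means they emulate:
#' forward-strength novel/repeated 1.21/0.99 (onto spiny stellate) and
#' 0.81/0.67 (onto deep pyramidal); gain novel/repeated 1.16/0.98; forward
#' delay means 9.18 ms (older-like) vs 7.98 ms (younger-like); base reaction
#' times 815.9/727.0 ms (older-like) and 679.1/608.8 ms (younger-like).
#'
#' @param group `"older"` or `"younger"`.
#' @param n_subjects cohort size (>= 2).
#' @param generative_model_id defaults to 2 for older-like, 3 for
#'   younger-like.
#' @param subject_sd between-subject standard deviation of log-scaling
#'   parameters (log-normal variation; default 0.15).
#' @param snr signal-to-noise ratio of emitted ERPs (signal RMS / noise SD).
#' @param hemispheres network variant (`"both"` = 8 sources; `"left"` = the
#'   reduced 4-source test network).
#' @param effects named list overriding any of `repetition_fss`,
#'   `repetition_fdp` (novel/repeated strength means on the EV->aVT forward
#'   components), `repetition_gain` (novel/repeated aVT gain means),
#'   `forward_delay_ms`, `frontal_input_mean`, `rt_base` (novel, repeated ms),
#'   `rt_target_r`, `rt_subject_sd`, `rt_condition_sd`, `rt_beta` (explicit
#'   ms-per-unit input-RT slope; when `NULL`, the slope is calibrated from
#'   `rt_target_r`).
#' @param seed integer master seed; per-subject streams are derived from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("older", "younger"), n_subjects = 15,
                        generative_model_id = NULL, subject_sd = 0.15,
                        snr = 5, hemispheres = "both", effects = list(),
                        seed = 1) {
  group <- match.arg(group)
  stopifnot(n_subjects >= 2, snr > 0, subject_sd >= 0)
  if (is.null(generative_model_id))
    generative_model_id <- if (group == "older") 2L else 3L
  stopifnot(generative_model_id %in% 1:3)

  defaults <- if (group == "older") list(
    repetition_fss = c(novel = 1.21, repeated = 0.99),
    repetition_fdp = c(novel = 0.81, repeated = 0.67),
    repetition_gain = NULL,
    forward_delay_ms = 9.18,
    frontal_input_mean = 1,
    rt_base = c(novel = 815.9, repeated = 727.0),
    rt_target_r = -0.39,
    rt_subject_sd = 90,
    rt_condition_sd = 27.2,
    rt_beta = NULL
  ) else list(
    repetition_fss = NULL,
    repetition_fdp = NULL,
    repetition_gain = c(novel = 1.16, repeated = 0.98),
    forward_delay_ms = 7.98,
    frontal_input_mean = 0,
    rt_base = c(novel = 679.1, repeated = 608.8),
    rt_target_r = 0,
    rt_subject_sd = 90,
    rt_condition_sd = 27.2,
    rt_beta = NULL
  )
  eff <- utils::modifyList(defaults, effects)

  structure(list(group = group, n_subjects = n_subjects,
                 generative_model_id = generative_model_id,
                 subject_sd = subject_sd, snr = snr,
                 hemispheres = hemispheres, effects = eff, seed = seed),
            class = "cohort_spec")
}

# deterministic per-subject sub-seed streams (kept < 2^31)
.subject_seed <- function(seed, subject_index, salt = 0) {
  s <- (as.numeric(seed) * 48271 + subject_index * 9973 + salt * 331) %%
    2147483629
  as.integer(s)
}

#' Group-mean generative parameters of a cohort
#'
#' The packed log-scaling vector around which subjects vary: repetition
#' effects as per-component modulations on the EV->aVT forward edges (older)
#' or on the aVT superficial-pyramidal gain (younger), forward delays at the
#' group mean, and frontal input strength for the older-like architecture.
#'
#' @param spec a [cohort_spec()].
#' @return list with `model` (the generative `dcm_network`), `pack`
#'   (its parameterization), `theta` (group-mean packed vector).
#' @export
cohort_group_means <- function(spec) {
  model <- build_model(spec$generative_model_id,
                       hemispheres = spec$hemispheres)
  pack <- pack_parameters(model)
  theta <- pack$theta0
  eff <- spec$effects
  nm <- model$sources$name
  src <- model$sources

  ev_avt <- paste0(nm[src$region == "EV"], "->", nm[src$region == "aVT"])
  # per-hemisphere EV->aVT labels actually present in the model
  fwd_lbl <- pack$ix$fwd$label
  ev_avt <- intersect(unlist(lapply(unique(src$hemisphere), function(h) {
    e <- nm[src$region == "EV" & src$hemisphere == h]
    a <- nm[src$region == "aVT" & src$hemisphere == h]
    paste0(e, "->", a)
  })), fwd_lbl)

  if (!is.null(eff$repetition_fss)) {
    # novel strength = default(1) * exp(A); repeated = novel * exp(B)
    for (lbl in ev_avt) {
      theta[paste0("A.fss.", lbl)] <- log(eff$repetition_fss[["novel"]])
      theta[paste0("A.fdp.", lbl)] <- log(eff$repetition_fdp[["novel"]])
      # the packed B is tied per edge; the generator carries per-component
      # modulations separately (see sample_subject_parameters)
    }
  }
  if (!is.null(eff$repetition_gain)) {
    avt <- nm[src$region == "aVT"]
    theta[paste0("G.", avt)] <- log(eff$repetition_gain[["novel"]])
  }

  # forward delays centred at the group mean (default edge delay 8 ms)
  dfwd <- paste0("D.", fwd_lbl)
  theta[dfwd] <- log(eff$forward_delay_ms / 8)

  if (eff$frontal_input_mean > 0 && any(grepl("^C\\..*IFG$", pack$names))) {
    cifg <- grep("^C\\..*IFG$", pack$names, value = TRUE)
    theta[cifg] <- log(eff$frontal_input_mean)
  }
  list(model = model, pack = pack, theta = theta)
}

# per-component generative condition modulations (novel -> repeated log drops)
.generative_b <- function(spec, model) {
  eff <- spec$effects
  b <- numeric(0)
  nm <- model$sources$name
  src <- model$sources
  if (!is.null(eff$repetition_fss)) {
    for (h in unique(src$hemisphere)) {
      e <- nm[src$region == "EV" & src$hemisphere == h]
      a <- nm[src$region == "aVT" & src$hemisphere == h]
      lbl <- paste0(e, "->", a)
      b[paste0("A.fss.", lbl)] <-
        log(eff$repetition_fss[["repeated"]] / eff$repetition_fss[["novel"]])
      b[paste0("A.fdp.", lbl)] <-
        log(eff$repetition_fdp[["repeated"]] / eff$repetition_fdp[["novel"]])
    }
  }
  if (!is.null(eff$repetition_gain)) {
    avt <- nm[src$region == "aVT"]
    b[paste0("G.", avt)] <-
      log(eff$repetition_gain[["repeated"]] / eff$repetition_gain[["novel"]])
  }
  b
}

#' Draw one subject's generative parameters
#'
#' Log-scaling parameters are drawn around the group means with standard
#' deviation `subject_sd` (log-normal on the physical scale), from a
#' deterministic per-subject stream.  The per-component condition modulations
#' receive the same treatment.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index 1-based subject index.
#' @param means optional precomputed [cohort_group_means()] (for speed in
#'   loops).
#' @return list with `subject` (id), `theta` (packed generative vector), `b`
#'   (named per-component condition modulations), `input_strength` (generative
#'   C at left IFG, or `NA` when the architecture has no frontal input),
#'   `model`, `pack`.
#' @export
sample_subject_parameters <- function(spec, subject_index,
                                      means = cohort_group_means(spec)) {
  stopifnot(inherits(spec, "cohort_spec"))
  sd <- spec$subject_sd
  b0 <- .generative_b(spec, means$model)
  seeds <- vapply(seq_len(spec$n_subjects),
                  function(i) .subject_seed(spec$seed, i), integer(1))
  if (anyDuplicated(seeds)) stop("seed collision across subject streams")
  theta <- local_seed(seeds[subject_index], {
    th <- means$theta + stats::rnorm(length(means$theta), 0, sd)
    bb <- b0 + if (length(b0)) stats::rnorm(length(b0), 0, sd) else numeric(0)
    list(th = th, bb = bb)
  })
  names(theta$th) <- names(means$theta)
  names(theta$bb) <- names(b0)
  # the inversion's own B slots stay at the tied-edge representation; the
  # generative per-component b is applied through apply_modulation instead
  th <- theta$th
  th[means$pack$classes == "B"] <- 0
  input_strength <- if ("C.lIFG" %in% names(th))
    unname(exp(th["C.lIFG"])) else NA_real_
  list(subject = sprintf("%s%02d", substr(spec$group, 1, 1), subject_index),
       index = subject_index,
       theta = th, b = theta$bb, input_strength = input_strength,
       model = means$model, pack = means$pack)
}

#' Simulate one subject's two-condition dataset
#'
#' Runs the forward model at the subject's generative parameters for the
#' novel condition and, with the per-component modulations applied, for the
#' repeated condition; adds Gaussian noise with SD = signal RMS / `snr`
#' (pooled over both conditions) from the subject's noise stream.  `snr =
#' Inf` disables noise and reproduces the deterministic forward simulation.
#'
#' @param subj output of [sample_subject_parameters()].
#' @param spec the [cohort_spec()].
#' @param grid a [simulation_grid()] (default 1-450 ms at 250 Hz).
#' @param input a [stimulus_input()].
#' @return an [erp_dataset()].
#' @export
simulate_subject <- function(subj, spec, grid = simulation_grid(),
                             input = stimulus_input()) {
  pack <- subj$pack
  u <- unpack_parameters(pack, subj$theta)
  net_nov <- .network_with(subj$model, u$novel)
  net_rep <- if (length(subj$b))
    apply_modulation(net_nov, condition_modulation(subj$b), "repeated")
  else net_nov
  prm <- pack$params
  prm_subj <- cmc_parameters(tau = u$tau, g = prm$g,
                             sigmoid_slope = prm$sigmoid_slope,
                             gain_sp = prm$gain_sp, ext_gain = prm$ext_gain)
  obs_subj <- observation_spec(contribution = pack$contribution,
                               channel_gain = u$gain)

  sim_err <- function(e) stop(sprintf("subject %s: %s", subj$subject,
                                      conditionMessage(e)), call. = FALSE)
  g_nov <- tryCatch(observe(integrate_network(net_nov, prm_subj, input, grid),
                            obs_subj), error = sim_err)
  g_rep <- tryCatch(observe(integrate_network(net_rep, prm_subj, input, grid),
                            obs_subj), error = sim_err)

  rms <- sqrt(mean(c(g_nov^2, g_rep^2)))
  noise_sd <- if (is.finite(spec$snr)) rms / spec$snr else 0
  if (noise_sd > 0) {
    nz <- local_seed(.subject_seed(spec$seed, subj$index, salt = 7),
                     matrix(stats::rnorm(2 * length(g_nov), 0, noise_sd),
                            nrow(g_nov)))
    g_nov <- g_nov + nz[, seq_len(ncol(g_nov))]
    g_rep <- g_rep + nz[, ncol(g_nov) + seq_len(ncol(g_rep))]
  }
  erp_dataset(g_nov, g_rep, grid$times, subject = subj$subject,
              sampling_rate_hz = grid$output_rate)
}

# clone a network with effective (physical) matrices from unpack_parameters
.network_with <- function(model, eff) {
  m <- model
  m$A_forward$ss <- eff$Afss; m$A_forward$dp <- eff$Afdp
  m$A_backward$sp <- eff$Absp; m$A_backward$ii <- eff$Abii
  m$C <- eff$C; m$D <- eff$D; m$D_self <- eff$D_self; m$G <- eff$G
  m
}

#' Generate behavioural records for a cohort
#'
#' Reaction times per condition are the group base RT minus a linear effect
#' of (input strength - group mean), plus subject- and condition-level
#' Gaussian noise.  For older-like cohorts the slope `beta` is calibrated
#' analytically from the target population correlation `rt_target_r` between
#' input strength and mean RT (given the log-normal input dispersion and the
#' RT noise SDs); younger-like RTs are uncoupled from inputs.
#'
#' @param subjects list from [sample_subject_parameters()].
#' @param spec the [cohort_spec()].
#' @return data frame with columns `subject`, `rt_novel`, `rt_repeated`,
#'   `input_strength`.
#' @export
generate_behavior <- function(subjects, spec) {
  n <- length(subjects)
  if (n < 3) stop("need >= 3 subjects to calibrate the input-RT correlation")
  eff <- spec$effects
  x <- vapply(subjects, function(s) s$input_strength, numeric(1))
  target_r <- eff$rt_target_r
  s_sub <- eff$rt_subject_sd
  s_cond <- eff$rt_condition_sd
  sd_mean_noise <- sqrt(s_sub^2 + s_cond^2 / 2)

  beta <- 0
  if (!is.null(eff$rt_beta)) {
    beta <- eff$rt_beta
  } else if (target_r != 0) {
    if (any(is.na(x))) stop("input strength undefined for this architecture")
    s <- spec$subject_sd
    mu <- eff$frontal_input_mean
    sd_x <- if (s > 0) mu * exp(s^2 / 2) * sqrt(exp(s^2) - 1) else 0
    if (sd_x == 0 && sd_mean_noise == 0) stop("degenerate calibration")
    # r = -beta sd_x / sqrt(beta^2 sd_x^2 + sd_noise^2), solved for beta
    a <- abs(target_r)
    beta <- if (sd_x > 0) a / sqrt(1 - a^2) * sd_mean_noise / sd_x else 0
    beta <- beta * -sign(target_r)   # rt = base - beta * x: beta > 0 gives r < 0
  }
  xc <- if (all(is.na(x))) rep(0, n) else x - mean(x)
  noise <- local_seed(.subject_seed(spec$seed, 0, salt = 13), {
    list(sub = stats::rnorm(n, 0, s_sub),
         nov = stats::rnorm(n, 0, s_cond),
         rep = stats::rnorm(n, 0, s_cond))
  })
  rt_novel <- eff$rt_base[["novel"]] - beta * xc + noise$sub + noise$nov
  rt_repeated <- eff$rt_base[["repeated"]] - beta * xc + noise$sub + noise$rep
  data.frame(subject = vapply(subjects, `[[`, "", "subject"),
             rt_novel = rt_novel, rt_repeated = rt_repeated,
             input_strength = x, stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Parameters, two-condition ERP datasets and behaviour for every subject;
#' byte-identical for identical spec + seed.
#'
#' @param spec a [cohort_spec()].
#' @param grid,input forward-model settings (see [simulate_subject()]).
#' @return object of class `dcm_cohort`: `spec`, `subjects` (generative
#'   parameter draws), `data` (list of [erp_dataset()]), `behavior` (data
#'   frame), `model` (generative network).
#' @export
generate_cohort <- function(spec, grid = simulation_grid(),
                            input = stimulus_input()) {
  means <- cohort_group_means(spec)
  subjects <- lapply(seq_len(spec$n_subjects), sample_subject_parameters,
                     spec = spec, means = means)
  data <- lapply(subjects, simulate_subject, spec = spec, grid = grid,
                 input = input)
  names(data) <- vapply(subjects, `[[`, "", "subject")
  behavior <- generate_behavior(subjects, spec)
  structure(list(spec = spec, subjects = subjects, data = data,
                 behavior = behavior, model = means$model),
            class = "dcm_cohort")
}

#' Write a cohort to disk
#'
#' Per-subject directories of ERP matrices, one behaviour TSV, and a JSON
#' manifest.
#'
#' @param cohort a `dcm_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in cohort$data) write_erp_dataset(d, file.path(dir, d$subject))
  utils::write.table(cohort$behavior, file.path(dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(group = cohort$spec$group,
                   n_subjects = cohort$spec$n_subjects,
                   generative_model_id = cohort$spec$generative_model_id,
                   snr = cohort$spec$snr, seed = cohort$spec$seed,
                   hemispheres = cohort$spec$hemispheres,
                   subjects = names(cohort$data),
                   sources = rownames(cohort$data[[1]]$novel),
                   sampling_rate_hz = cohort$data[[1]]$sampling_rate_hz)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
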