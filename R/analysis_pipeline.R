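#' Harvest physical-scale parameter estimates from fitted posteriors
#'
#' Long-format table of posterior parameter estimates on the physical scale,
#' by class: `C` input gains, `B` condition-resolved effective values (novel
#' and repeated rows for every modulated parameter, per extrinsic component
#' and per-source gain), `G` baseline superficial-pyramidal gains, `D`
#' conduction delays in ms (forward, backward and self, tagged in `kind`).
#'
#' @param posteriors list of `dcm_posterior` for one model across subjects.
#' @param model the fitted `dcm_network`.
#' @param classes subset of `c("C", "B", "G", "D")`.
#' @param group optional group label column.
#' @return data frame (`harvest_table`) with columns `subject`, `group`,
#'   `model_id`, `class`, `parameter`, `condition`, `kind`, `value`.
#' @export
harvest_parameters <- function(posteriors, model,
                               classes = c("C", "B", "G", "D"),
                               group = NA_character_) {
  stopifnot(length(posteriors) >= 1)
  bad <- setdiff(classes, c("C", "B", "G", "D"))
  if (length(bad)) stop("unknown harvest class: ", paste(bad, collapse = ", "))
  mids <- unique(vapply(posteriors, function(p) p$model_id, numeric(1)))
  if (length(mids) != 1) stop("posteriors must come from a single model")
  pack <- pack_parameters(model)
  avail <- unique(pack$classes)
  missing_cl <- setdiff(classes, avail)
  if (length(missing_cl))
    stop("requested class absent from model: ", paste(missing_cl, collapse = ", "))

  fwd <- pack$ix$fwd$label; bwd <- pack$ix$bwd$label
  nm <- model$sources$name

  one <- function(post) {
    ep <- post$Ep
    rows <- list()
    if ("C" %in% classes) {
      cn <- grep("^C\\.", names(ep), value = TRUE)
      rows$C <- data.frame(class = "C", parameter = cn,
                           condition = NA_character_, kind = NA_character_,
                           value = unname(exp(ep[cn])))
    }
    if ("B" %in% classes) {
      comp <- c("fss", "fdp"); bcomp <- c("bsp", "bii")
      out <- list()
      for (lbl in fwd) {
        b <- ep[paste0("B.", lbl)]
        for (cc in comp) {
          a <- ep[paste0("A.", cc, ".", lbl)]
          out[[length(out) + 1]] <- data.frame(
            class = "B", parameter = paste0("A.", cc, ".", lbl),
            condition = c("novel", "repeated"), kind = "forward",
            value = c(exp(a), exp(a + b)))
        }
      }
      for (lbl in bwd) {
        b <- ep[paste0("B.", lbl)]
        for (cc in bcomp) {
          a <- ep[paste0("A.", cc, ".", lbl)]
          out[[length(out) + 1]] <- data.frame(
            class = "B", parameter = paste0("A.", cc, ".", lbl),
            condition = c("novel", "repeated"), kind = "backward",
            value = c(exp(a), exp(a + b)))
        }
      }
      for (s in nm) {
        g <- ep[paste0("G.", s)]
        bg <- ep[paste0("B.G.", s)]
        out[[length(out) + 1]] <- data.frame(
          class = "B", parameter = paste0("G.", s),
          condition = c("novel", "repeated"), kind = "gain",
          value = c(exp(g), exp(g + bg)))
      }
      rows$B <- do.call(rbind, out)
    }
    if ("G" %in% classes) {
      gn <- paste0("G.", nm)
      rows$G <- data.frame(class = "G", parameter = gn,
                           condition = NA_character_, kind = "gain",
                           value = unname(exp(ep[gn])))
    }
    if ("D" %in% classes) {
      dfw <- model$D[pack$ix$fwd$lin] * exp(ep[paste0("D.", fwd)])
      dbw <- model$D[pack$ix$bwd$lin] * exp(ep[paste0("D.", bwd)])
      dsf <- model$D_self * exp(ep[paste0("D.self.", nm)])
      rows$D <- data.frame(
        class = "D",
        parameter = c(paste0("D.", fwd), paste0("D.", bwd),
                      paste0("D.self.", nm)),
        condition = NA_character_,
        kind = c(rep("forward", length(fwd)), rep("backward", length(bwd)),
                 rep("self", length(nm))),
        value = unname(c(dfw, dbw, dsf)))
    }
    out <- do.call(rbind, rows)
    out$subject <- post$subject
    out
  }

  tab <- do.call(rbind, lapply(posteriors, one))
  tab$group <- group
  tab$model_id <- mids
  rownames(tab) <- NULL
  tab <- tab[, c("subject", "group", "model_id", "class", "parameter",
                 "condition", "kind", "value")]
  class(tab) <- c("harvest_table", "data.frame")
  tab
}

#' Names of the ventral-stream condition-modulated parameters
#'
#' The ventral route runs from early visual cortex through anterior ventral
#' temporal cortex to the inferior frontal gyrus; repetition effects are
#' examined on its extrinsic components and on the superficial-pyramidal
#' gains of its sources.
#'
#' @param model a `dcm_network`.
#' @return character vector of harvested `B`-class parameter names.
#' @export
ventral_stream_parameters <- function(model) {
  src <- model$sources
  vs <- src$name[src$region %in% c("EV", "aVT", "IFG")]
  pack <- pack_parameters(model)
  lbls <- c(pack$ix$fwd$label, pack$ix$bwd$label)
  on_route <- function(lbl) {
    ft <- strsplit(lbl, "->", fixed = TRUE)[[1]]
    all(ft %in% vs)
  }
  edge <- lbls[vapply(lbls, on_route, logical(1))]
  comp <- unlist(lapply(edge, function(lbl) {
    pre <- if (lbl %in% pack$ix$fwd$label) c("fss", "fdp") else c("bsp", "bii")
    paste0("A.", pre, ".", lbl)
  }))
  c(comp, paste0("G.", src$name[src$region == "aVT"]))
}

#' Behavioural priming effect
#'
#' Novel minus repeated mean reaction time, in ms.
#'
#' @param rt_novel,rt_repeated mean reaction times (ms, > 0); vectorized.
#' @return `rt_novel - rt_repeated`.
#' @export
priming_effect <- function(rt_novel, rt_repeated) {
  stopifnot(all(rt_novel > 0), all(rt_repeated > 0))
  rt_novel - rt_repeated
}

#' Correlate frontal input strength with naming speed
#'
#' Pearson correlation (two-sided) between the harvested driving-input gain at
#' left inferior frontal gyrus and per-subject mean reaction time (mean of the
#' novel and repeated conditions).
#'
#' @param harvest a harvest table containing `C`-class rows, or a named
#'   numeric vector of input strengths by subject.
#' @param behavior data frame with `subject`, `rt_novel`, `rt_repeated`.
#' @param parameter which input gain to use (default `"C.lIFG"`).
#' @return list with `r`, `p`, `df`, `n`, and the fitted `cor.test` object.
#' @export
correlate_input_behavior <- function(harvest, behavior,
                                     parameter = "C.lIFG") {
  if (is.data.frame(harvest)) {
    rows <- harvest[harvest$class == "C" & harvest$parameter == parameter, ]
    if (!nrow(rows)) stop("no harvested rows for ", parameter)
    x <- stats::setNames(rows$value, rows$subject)
  } else {
    x <- harvest
  }
  rt <- (behavior$rt_novel + behavior$rt_repeated) / 2
  names(rt) <- behavior$subject
  common <- intersect(names(x), names(rt))
  if (length(common) < 3) stop("need >= 3 paired observations")
  x <- x[common]; rt <- rt[common]
  if (stats::sd(x) == 0 || stats::sd(rt) == 0)
    stop("zero variance in input strength or reaction time")
  ct <- stats::cor.test(x, rt, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(common), test = ct)
}

#' Test repetition effects on modulated parameters
#'
#' One-sample t-tests of the subject-wise novel-minus-repeated contrast of
#' each condition-modulated parameter against zero, with multiplicity
#' correction across the tested parameters.
#'
#' @param harvest harvest table restricted to the `B`-class rows of interest
#'   (e.g. [ventral_stream_parameters()]).
#' @param correction `"bonferroni"`, `"holm"` or `"fdr"` (BH).
#' @return data frame per parameter: mean novel and repeated values, mean
#'   contrast, `t`, `df`, `p`, `p_corrected`.
#' @export
test_repetition_effects <- function(harvest,
                                    correction = c("bonferroni", "holm", "fdr")) {
  correction <- match.arg(correction)
  b <- harvest[harvest$class == "B", ]
  if (!nrow(b)) stop("no B-class rows in harvest")
  if (length(unique(b$subject)) < 2) stop("need >= 2 subjects")
  wide <- stats::reshape(b[, c("subject", "parameter", "condition", "value")],
                         idvar = c("subject", "parameter"),
                         timevar = "condition", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  out <- do.call(rbind, lapply(split(wide, wide$parameter), function(d) {
    contrast <- d$novel - d$repeated
    if (stats::sd(contrast) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = nrow(d) - 1),
                 p.value = 1)
      if (any(contrast != 0)) tt$p.value <- 0   # constant non-zero contrast
    } else {
      tt <- stats::t.test(contrast)
    }
    data.frame(parameter = d$parameter[1],
               mean_novel = mean(d$novel), mean_repeated = mean(d$repeated),
               mean_contrast = mean(contrast),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  method <- c(bonferroni = "bonferroni", holm = "holm", fdr = "BH")[correction]
  out$p_corrected <- stats::p.adjust(out$p, method = method)
  rownames(out) <- NULL
  out
}

#' Compare conduction delays between groups
#'
#' Per delay class (forward, backward, self): average each subject's delays,
#' then a two-sample Welch t-test between groups.
#'
#' @param harvest_a,harvest_b harvest tables with `D`-class rows for the two
#'   groups (e.g. older, younger).
#' @return data frame per class: group means (a, b), `t`, `df`, `p`.
#' @export
compare_group_delays <- function(harvest_a, harvest_b) {
  per_subject <- function(h) {
    d <- h[h$class == "D", ]
    if (!nrow(d)) stop("no D-class rows in harvest")
    stats::aggregate(value ~ subject + kind, d, mean)
  }
  a <- per_subject(harvest_a); b <- per_subject(harvest_b)
  kinds <- union(unique(a$kind), unique(b$kind))
  out <- do.call(rbind, lapply(kinds, function(k) {
    xa <- a$value[a$kind == k]; xb <- b$value[b$kind == k]
    if (!length(xa) || !length(xb)) stop("delay class missing in a group: ", k)
    if (length(xa) < 2 || length(xb) < 2) stop("singleton group for class ", k)
    if (stats::sd(c(xa, xb)) == 0) {
      data.frame(kind = k, mean_a = mean(xa), mean_b = mean(xb),
                 t = 0, df = length(xa) + length(xb) - 2, p = 1)
    } else {
      tt <- stats::t.test(xa, xb)
      data.frame(kind = k, mean_a = mean(xa), mean_b = mean(xb),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Study manifest
#'
#' Bundles cohorts, the model space and analysis options into one reproducible
#' unit for [run_study()].
#'
#' @param groups named list of `dcm_cohort` objects (or directories written by
#'   [write_cohort()]; these are read back with their manifest).
#' @param model_ids models to invert (default 1:3).
#' @param priors a [prior_spec()].
#' @param fit_threshold re-initialization threshold (0.75).
#' @param correction multiplicity correction for repetition tests.
#' @param alpha significance level (0.05, two-sided).
#' @param seed seed for the exceedance sampler.
#' @param n_samples Dirichlet draws for exceedance probabilities.
#' @param control inversion control overrides (see [variational_laplace()]).
#' @return object of class `study_manifest`.
#' @export
study_manifest <- function(groups, model_ids = 1:3, priors = prior_spec(),
                           fit_threshold = 0.75,
                           correction = "bonferroni", alpha = 0.05,
                           seed = 1, n_samples = 1e6, control = list()) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  structure(list(groups = groups, model_ids = model_ids, priors = priors,
                 fit_threshold = fit_threshold, correction = correction,
                 alpha = alpha, seed = seed, n_samples = n_samples,
                 control = control),
            class = "study_manifest")
}

#' Read a study manifest from JSON
#'
#' The on-disk manifest names cohort directories (written by
#' [write_cohort()]) per group and carries the analysis options; paths are
#' resolved relative to the manifest file.
#'
#' @param path JSON file with fields `groups` (map of group label to cohort
#'   directory) and optionally `model_ids`, `fit_threshold`, `correction`,
#'   `alpha`, `seed`, `n_samples`.
#' @return a [study_manifest()].
#' @export
read_study_manifest <- function(path) {
  x <- jsonlite::fromJSON(path)
  stopifnot(!is.null(x$groups))
  base <- dirname(normalizePath(path))
  groups <- lapply(x$groups, function(p)
    if (dir.exists(p)) p else file.path(base, p))
  study_manifest(groups,
                 model_ids = x$model_ids %||% 1:3,
                 fit_threshold = x$fit_threshold %||% 0.75,
                 correction = x$correction %||% "bonferroni",
                 alpha = x$alpha %||% 0.05,
                 seed = x$seed %||% 1,
                 n_samples = x$n_samples %||% 1e6)
}

.load_cohort <- function(g) {
  if (inherits(g, "dcm_cohort")) return(g)
  if (is.character(g) && dir.exists(g)) {
    man <- jsonlite::fromJSON(file.path(g, "manifest.json"))
    data <- lapply(man$subjects, function(s) read_erp_dataset(file.path(g, s)))
    names(data) <- man$subjects
    behavior <- utils::read.delim(file.path(g, "behavior.tsv"))
    return(structure(list(spec = NULL, subjects = NULL, data = data,
                          behavior = behavior, model = NULL,
                          manifest = man),
                     class = "dcm_cohort"))
  }
  stop("group must be a dcm_cohort or a cohort directory")
}

#' Run the full study pipeline
#'
#' For each group: invert every model per subject, re-initialize and refit
#' low-fit inversions, build the evidence table, run family-level and
#' within-family model-level random-effects BMS, select the winning model
#' (highest model-level exceedance within the winning family), and harvest its
#' parameters.  Then compute the group statistics: priming effects and group
#' t-tests, the frontal input/naming-speed correlation (per group with frontal
#' input in the winning model), repetition-effect tests on the ventral stream,
#' and the between-group conduction-delay comparison.  Deterministic given the
#' manifest seed.
#'
#' @param manifest a [study_manifest()].
#' @param hemispheres network variant used for the inverted models; defaults
#'   to the hemisphere set of the first cohort's generative model when
#'   available, else `"both"`.
#' @param progress print stage messages.
#' @param checkpoint_dir optional directory: per-(group, model) inversion
#'   results are saved there as they complete and reused on a rerun, so an
#'   aborted study resumes instead of restarting.
#' @return object of class `study_report`.
#' @export
run_study <- function(manifest, hemispheres = NULL, progress = interactive(),
                      checkpoint_dir = NULL) {
  stopifnot(inherits(manifest, "study_manifest"))
  if (!is.null(checkpoint_dir))
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  cohorts <- lapply(manifest$groups, .load_cohort)
  if (is.null(hemispheres)) {
    hemispheres <- "both"
    m0 <- cohorts[[1]]$model
    if (!is.null(m0)) {
      h <- unique(m0$sources$hemisphere)
      if (length(h) == 1) hemispheres <- h
    } else if (!is.null(cohorts[[1]]$manifest$hemispheres)) {
      hemispheres <- cohorts[[1]]$manifest$hemispheres
    }
  }
  models <- lapply(manifest$model_ids, build_model, hemispheres = hemispheres)
  names(models) <- as.character(manifest$model_ids)
  partition <- family_partition(models)

  say <- function(...) if (progress) message(sprintf(...))
  groups <- list()
  for (gname in names(cohorts)) {
    co <- cohorts[[gname]]
    posts <- list()
    for (mid in names(models)) {
      ck <- if (!is.null(checkpoint_dir))
        file.path(checkpoint_dir, sprintf("%s_model%s.rds", gname, mid))
      if (!is.null(ck) && file.exists(ck)) {
        say("group %s: model %s restored from checkpoint", gname, mid)
        posts[[mid]] <- readRDS(ck)
        next
      }
      say("group %s: inverting model %s over %d subjects", gname, mid,
          length(co$data))
      posts[[mid]] <- invert_cohort(co$data, models[[mid]],
                                    threshold = manifest$fit_threshold,
                                    priors = manifest$priors,
                                    control = manifest$control)
      if (!is.null(ck)) saveRDS(posts[[mid]], ck)
    }
    Fm <- vapply(posts, function(pl) vapply(pl, function(p) p$F, numeric(1)),
                 numeric(length(co$data)))
    Fm <- matrix(Fm, nrow = length(co$data),
                 dimnames = list(names(co$data), names(models)))
    tab <- evidence_table(Fm, group = gname)
    fam <- family_bms(tab, partition, n_samples = manifest$n_samples,
                      seed = manifest$seed)
    win_family <- names(which.max(fam$exceedance_prob))
    members <- as.character(partition[[win_family]])
    if (length(members) > 1) {
      sub_tab <- evidence_table(Fm[, members, drop = FALSE], group = gname)
      within <- rfx_bms(sub_tab, n_samples = manifest$n_samples,
                        seed = manifest$seed)
      win_model <- names(which.max(within$exceedance_prob))
    } else {
      within <- NULL
      win_model <- members
    }
    harvest <- harvest_parameters(posts[[win_model]], models[[win_model]],
                                  group = gname)
    fits <- vapply(posts[[win_model]], function(p) p$fit, numeric(1))
    groups[[gname]] <- list(
      evidence = tab, family_bms = fam, within_family_bms = within,
      winning_family = win_family, winning_model = win_model,
      harvest = harvest, fits = fits, posteriors = posts,
      behavior = co$behavior)
  }

  # behavioural statistics
  beh <- lapply(names(groups), function(g) {
    b <- groups[[g]]$behavior
    pr <- priming_effect(b$rt_novel, b$rt_repeated)
    data.frame(group = g, n = nrow(b),
               rt_novel = mean(b$rt_novel), rt_repeated = mean(b$rt_repeated),
               priming = mean(pr), priming_se = stats::sd(pr) / sqrt(nrow(b)))
  })
  beh <- do.call(rbind, beh)
  group_tests <- NULL
  if (length(groups) == 2) {
    b1 <- groups[[1]]$behavior; b2 <- groups[[2]]$behavior
    tt <- function(x, y) {
      h <- stats::t.test(x, y)
      c(t = unname(h$statistic), p = h$p.value)
    }
    group_tests <- rbind(
      novel = tt(b1$rt_novel, b2$rt_novel),
      repeated = tt(b1$rt_repeated, b2$rt_repeated),
      priming = tt(priming_effect(b1$rt_novel, b1$rt_repeated),
                   priming_effect(b2$rt_novel, b2$rt_repeated)))
  }

  input_rt <- lapply(groups, function(gr) {
    if (!any(gr$harvest$class == "C" & gr$harvest$parameter == "C.lIFG"))
      return(NULL)
    correlate_input_behavior(gr$harvest, gr$behavior)
  })

  repetition <- lapply(names(groups), function(g) {
    gr <- groups[[g]]
    mid <- gr$winning_model
    vs <- ventral_stream_parameters(models[[mid]])
    h <- gr$harvest
    h <- h[h$class == "B" & h$parameter %in% vs, ]
    cbind(group = g, test_repetition_effects(h, manifest$correction))
  })
  names(repetition) <- names(groups)

  delays <- NULL
  if (length(groups) == 2)
    delays <- compare_group_delays(groups[[1]]$harvest, groups[[2]]$harvest)

  structure(list(
    groups = groups, models = models, partition = partition,
    behavior = beh, behavior_group_tests = group_tests,
    input_rt = input_rt, repetition = repetition, delays = delays,
    provenance = list(
      package_version = as.character(utils::packageVersion("microdcm")),
      seed = manifest$seed, model_ids = manifest$model_ids,
      fit_threshold = manifest$fit_threshold,
      correction = manifest$correction, alpha = manifest$alpha,
      hemispheres = hemispheres)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("  %s: winning family %s, winning model %s (median fit %.3f)\n",
                g, gr$winning_family, gr$winning_model,
                stats::median(gr$fits)))
    cat("    family exceedance:",
        paste(sprintf("%s=%.3f", names(gr$family_bms$exceedance_prob),
                      gr$family_bms$exceedance_prob), collapse = " "), "\n")
    if (!is.null(gr$within_family_bms))
      cat("    within-family exceedance:",
          paste(sprintf("%s=%.3f", names(gr$within_family_bms$exceedance_prob),
                        gr$within_family_bms$exceedance_prob),
                collapse = " "), "\n")
  }
  if (!is.null(x$delays)) {
    cat("  forward-delay contrast: ")
    fd <- x$delays[x$delays$kind == "forward", ]
    cat(sprintf("%.2f vs %.2f ms (t = %.2f, p = %.3g)\n",
                fd$mean_a, fd$mean_b, fd$t, fd$p))
  }
  invisible(x)
}
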