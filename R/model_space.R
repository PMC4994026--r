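#' Source table of the object-naming network
#'
#' The eight cortical sources (four regions bilaterally) with their MNI
#' coordinates: early visual cortex (EV), anterior ventral temporal cortex
#' (aVT), angular gyrus (AG) and inferior frontal gyrus (IFG).
#'
#' @param hemispheres `"both"`, `"left"` or `"right"`; single-hemisphere
#'   variants give the reduced 4-source test network.
#' @return data frame with columns `name`, `region`, `hemisphere`, `x`, `y`,
#'   `z`.
#' @export
naming_network_sources <- function(hemispheres = c("both", "left", "right")) {
  hemispheres <- match.arg(hemispheres)
  src <- data.frame(
    name = c("lEV", "rEV", "laVT", "raVT", "lAG", "rAG", "lIFG", "rIFG"),
    region = rep(c("EV", "aVT", "AG", "IFG"), each = 2),
    hemisphere = rep(c("left", "right"), 4),
    x = c(-34, 34, -46, 46, -60, 56, -50, 48),
    y = c(-94, -92, -6, -8, -31, -36, 30, 36),
    z = c(-6, 2, -32, -32, 20, 18, -2, 6),
    stringsAsFactors = FALSE
  )
  if (hemispheres != "both") src <- src[src$hemisphere == hemispheres, ]
  rownames(src) <- NULL
  src
}

.edge_matrix <- function(edges, src_names, value = 1) {
  m <- matrix(0, length(src_names), length(src_names),
              dimnames = list(src_names, src_names))
  if (nrow(edges)) m[cbind(edges$to, edges$from)] <- value
  m
}

.edges_of <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  data.frame(from = colnames(m)[idx[, 2]], to = rownames(m)[idx[, 1]],
             stringsAsFactors = FALSE)
}

#' Build one of the three competing network architectures
#'
#' All models share the object-naming hierarchy: forward connections
#' EV -> AG and EV -> aVT, then AG -> IFG and aVT -> IFG (per hemisphere),
#' each with a reciprocal backward connection.  They differ only in where the
#' exogenous input enters and whether a fast feedforward shortcut to frontal
#' cortex exists:
#'
#' * model 1 — input to EV only (family 1: traditional bottom-up hierarchy);
#' * model 2 — input to EV and IFG (family 2: direct subcortical drive to
#'   frontal cortex);
#' * model 3 — input to EV only, plus a direct feedforward EV -> IFG edge
#'   with no reciprocal backward partner (family 2).
#'
#' Connection strengths are dimensionless scales (1 on every present edge);
#' the per-ms physical coupling is `strength * ext_gain` (see
#' [cmc_parameters()]).  Forward edges carry two components (onto spiny
#' stellate and deep pyramidal cells of the target), backward edges two
#' inhibitory components (onto superficial pyramidal and inhibitory
#' interneurons).
#'
#' @param model_id 1, 2 or 3.
#' @param hemispheres `"both"` (8 sources) or `"left"`/`"right"` (reduced
#'   4-source test network).
#' @param extrinsic_delay_ms default conduction delay on every extrinsic edge.
#' @param self_delay_ms default per-source (intrinsic) delay.
#' @return An object of class `dcm_network` with fields `sources`,
#'   `A_forward` (`$ss`, `$dp`), `A_backward` (`$sp`, `$ii`), `C`, `D`,
#'   `D_self`, `G` (per-source gain scale), `B_mask`, `family_id`, `model_id`.
#' @export
build_model <- function(model_id, hemispheres = c("both", "left", "right"),
                        extrinsic_delay_ms = 8, self_delay_ms = 1) {
  if (!(length(model_id) == 1 && model_id %in% 1:3))
    stop("unknown model_id: ", paste(model_id, collapse = ","))
  hemispheres <- match.arg(hemispheres)
  src <- naming_network_sources(hemispheres)
  nm <- src$name

  hemi_edges <- function(h) {
    p <- if (h == "left") "l" else "r"
    data.frame(
      from = paste0(p, c("EV", "EV", "AG", "aVT")),
      to   = paste0(p, c("AG", "aVT", "IFG", "IFG")),
      stringsAsFactors = FALSE)
  }
  hs <- unique(src$hemisphere)
  fwd <- do.call(rbind, lapply(hs, hemi_edges))
  bwd <- data.frame(from = fwd$to, to = fwd$from, stringsAsFactors = FALSE)
  if (model_id == 3) {
    extra <- do.call(rbind, lapply(hs, function(h) {
      p <- if (h == "left") "l" else "r"
      data.frame(from = paste0(p, "EV"), to = paste0(p, "IFG"),
                 stringsAsFactors = FALSE)
    }))
    fwd <- rbind(fwd, extra)
  }

  Af <- .edge_matrix(fwd, nm)
  Ab <- .edge_matrix(bwd, nm)
  D <- (Af + Ab) * extrinsic_delay_ms
  if (any(Af * Ab != 0))
    stop("forward and backward supports must be disjoint per direction")

  C <- stats::setNames(numeric(length(nm)), nm)
  input_regions <- if (model_id == 2) c("EV", "IFG") else "EV"
  C[src$region %in% input_regions] <- 1

  model <- structure(list(
    sources = src,
    A_forward = list(ss = Af, dp = Af),
    A_backward = list(sp = Ab, ii = Ab),
    C = C,
    D = D,
    D_self = stats::setNames(rep(self_delay_ms, length(nm)), nm),
    G = stats::setNames(rep(1, length(nm)), nm),
    model_id = model_id,
    family_id = if (model_id == 1) 1L else 2L
  ), class = "dcm_network")
  model$B_mask <- modulable_parameters(model)
  model
}

#' Construct an arbitrary network model
#'
#' Low-level constructor for user-defined architectures (the canonical three
#' come from [build_model()]).  Forward and backward edge sets must be
#' disjoint within their direction convention; every extrinsic edge gets a
#' positive conduction delay.
#'
#' @param sources data frame with at least a `name` column (optionally
#'   `region`, `hemisphere`, `x`, `y`, `z`).
#' @param forward,backward data frames with columns `from`, `to` and
#'   optionally `strength` (default 1).
#' @param C named input gains (defaults to 0 everywhere).
#' @param extrinsic_delay_ms,self_delay_ms delays in ms; `extrinsic_delay_ms`
#'   may be a single value or a vector matching the rows of
#'   `rbind(forward, backward)`.
#' @param model_id,family_id optional identifiers.
#' @return a `dcm_network`.
#' @export
network_model <- function(sources, forward, backward = NULL, C = NULL,
                          extrinsic_delay_ms = 8, self_delay_ms = 1,
                          model_id = NA_integer_, family_id = NA_integer_) {
  if (is.character(sources)) sources <- data.frame(name = sources,
                                                   stringsAsFactors = FALSE)
  nm <- sources$name
  if (is.null(backward)) backward <- forward[0, c("from", "to")]
  fs <- if (is.null(forward$strength)) rep(1, nrow(forward)) else forward$strength
  bs <- if (is.null(backward$strength)) rep(1, nrow(backward)) else backward$strength
  Af <- .edge_matrix(forward, nm, fs)
  Ab <- .edge_matrix(backward, nm, bs)
  if (any(Af * Ab != 0))
    stop("forward and backward supports must be disjoint per direction")
  d <- rep_len(extrinsic_delay_ms, nrow(forward) + nrow(backward))
  if (any(d <= 0)) stop("every delayed edge must have D > 0")
  D <- .edge_matrix(rbind(forward[, c("from", "to")], backward[, c("from", "to")]),
                    nm, d)
  Cv <- stats::setNames(numeric(length(nm)), nm)
  if (!is.null(C)) Cv[names(C)] <- C
  model <- structure(list(
    sources = sources,
    A_forward = list(ss = Af, dp = Af),
    A_backward = list(sp = Ab, ii = Ab),
    C = Cv, D = D,
    D_self = stats::setNames(rep(self_delay_ms, length(nm)), nm),
    G = stats::setNames(rep(1, length(nm)), nm),
    model_id = model_id, family_id = family_id
  ), class = "dcm_network")
  model$B_mask <- modulable_parameters(model)
  model
}

#' Names of all connection-strength parameters of a network
#'
#' One name per extrinsic component (`A.<comp>.<from>-><to>`, components
#' `fss`, `fdp`, `bsp`, `bii`) in a fixed order.
#' @param model a `dcm_network`.
#' @return character vector.
#' @export
strength_parameter_names <- function(model) {
  comp_names <- function(m, tag) {
    e <- .edges_of(m)
    if (!nrow(e)) return(character(0))
    paste0("A.", tag, ".", e$from, "->", e$to)
  }
  c(comp_names(model$A_forward$ss, "fss"), comp_names(model$A_forward$dp, "fdp"),
    comp_names(model$A_backward$sp, "bsp"), comp_names(model$A_backward$ii, "bii"))
}

#' Parameters eligible for condition modulation
#'
#' Following the design of the modulatory (`B`) effects: all extrinsic
#' connection strengths plus the superficial-pyramidal gain of every source.
#' Input gains `C`, delays `D` and time constants are never modulated.
#'
#' @param model a `dcm_network`.
#' @return character vector of parameter names.
#' @export
modulable_parameters <- function(model) {
  c(strength_parameter_names(model), paste0("G.", model$sources$name))
}

#' Condition modulation (B parameters)
#'
#' Log-scaling deviations applied to the repeated condition: each modulated
#' parameter is multiplied by `exp(b)` relative to its novel-condition
#' (baseline) value.  `b` may only address parameters in the model's `B_mask`.
#'
#' @param b named numeric vector of log-scaling deviations.
#' @return object of class `condition_modulation`.
#' @export
condition_modulation <- function(b = numeric(0)) {
  stopifnot(is.numeric(b), all(is.finite(b)))
  if (length(b) && is.null(names(b))) stop("b must be named")
  structure(list(b = b), class = "condition_modulation")
}

.set_strength <- function(model, name, mult) {
  parts <- strsplit(sub("^A\\.", "", name), ".", fixed = TRUE)[[1]]
  comp <- parts[1]
  ft <- strsplit(parts[2], "->", fixed = TRUE)[[1]]
  slot <- switch(comp, fss = c("A_forward", "ss"), fdp = c("A_forward", "dp"),
                 bsp = c("A_backward", "sp"), bii = c("A_backward", "ii"),
                 stop("unknown strength component: ", comp))
  model[[slot[1]]][[slot[2]]][ft[2], ft[1]] <-
    model[[slot[1]]][[slot[2]]][ft[2], ft[1]] * mult
  model
}

#' Apply a condition modulation to a network model
#'
#' The novel condition uses the baseline parameters; the repeated condition
#' multiplies each modulated parameter by `exp(b)`.
#'
#' @param model a `dcm_network`.
#' @param mod a [condition_modulation()].
#' @param condition `"novel"` or `"repeated"`.
#' @return the effective `dcm_network` for that condition.
#' @export
apply_modulation <- function(model, mod, condition = c("novel", "repeated")) {
  condition <- match.arg(condition)
  stopifnot(inherits(model, "dcm_network"), inherits(mod, "condition_modulation"))
  bad <- setdiff(names(mod$b), model$B_mask)
  if (length(bad))
    stop("modulation on parameters outside B_mask: ", paste(bad, collapse = ", "))
  if (condition == "novel" || !length(mod$b)) return(model)
  for (nm in names(mod$b)) {
    mult <- exp(mod$b[[nm]])
    if (startsWith(nm, "G.")) {
      s <- sub("^G\\.", "", nm)
      model$G[s] <- model$G[s] * mult
    } else {
      model <- .set_strength(model, nm, mult)
    }
  }
  model
}

#' Partition a model list into families
#'
#' @param models list of `dcm_network` objects with distinct `model_id`s and
#'   set `family_id`s.
#' @return named list mapping family id to the vector of member model ids
#'   (exhaustive and disjoint).
#' @export
family_partition <- function(models) {
  stopifnot(length(models) >= 1)
  ids <- vapply(models, function(m) m$model_id, numeric(1))
  fam <- lapply(models, function(m) m$family_id)
  if (any(vapply(fam, is.null, logical(1))))
    stop("model with unset family_id")
  fam <- unlist(fam)
  if (anyDuplicated(ids)) stop("duplicate model_id in model list")
  out <- split(ids, fam)
  lapply(out, unname)
}

#' Serialize a network model to JSON
#' @param model a `dcm_network`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return path (invisibly) or JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  x <- list(
    sources = model$sources,
    forward_ss = .strength_df(model$A_forward$ss),
    forward_dp = .strength_df(model$A_forward$dp),
    backward_sp = .strength_df(model$A_backward$sp),
    backward_ii = .strength_df(model$A_backward$ii),
    C = as.list(model$C),
    D = .strength_df(model$D),
    D_self = as.list(model$D_self),
    G = as.list(model$G),
    B_mask = model$B_mask,
    model_id = model$model_id,
    family_id = model$family_id
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

.strength_df <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  data.frame(from = colnames(m)[idx[, 2]], to = rownames(m)[idx[, 1]],
             value = m[idx], stringsAsFactors = FALSE)
}

#' Deserialize a network model from JSON
#' @param path file path or a JSON string produced by [model_to_json()].
#' @return a `dcm_network`.
#' @export
model_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  nm <- x$sources$name
  mat <- function(df) {
    m <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
    if (!is.null(df) && NROW(df)) m[cbind(df$to, df$from)] <- df$value
    m
  }
  structure(list(
    sources = as.data.frame(x$sources, stringsAsFactors = FALSE),
    A_forward = list(ss = mat(x$forward_ss), dp = mat(x$forward_dp)),
    A_backward = list(sp = mat(x$backward_sp), ii = mat(x$backward_ii)),
    C = unlist(x$C)[nm],
    D = mat(x$D),
    D_self = unlist(x$D_self)[nm],
    G = unlist(x$G)[nm],
    model_id = x$model_id,
    family_id = as.integer(x$family_id),
    B_mask = unlist(x$B_mask)
  ), class = "dcm_network")
}

#' Input-receiving sources of a model
#' @param model a `dcm_network`.
#' @return character vector of source names with `C > 0`.
#' @export
input_sources <- function(model) names(model$C)[model$C > 0]
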