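#' Scale definitions for the explicit attitude questionnaires
#'
#' Built-in definitions: NGRO (normative gender role orientation, 29 items,
#' responses 1-7) and the two 11-item subscales of the Ambivalent Sexism
#' Inventory, benevolent (ASI-BS) and hostile (ASI-HS), responses 0-5.
#' Reverse-keyed items default to none and are configurable.
#'
#' @param name Scale name.
#' @param n_items Number of items.
#' @param bounds Integer response bounds `c(min, max)`.
#' @param reverse Integer indices of reverse-coded items.
#' @return List of class `scale_definition`.
#' @export
scale_definition <- function(name, n_items, bounds, reverse = integer(0)) {
  if (bounds[1] >= bounds[2]) stop("bounds must satisfy min < max")
  if (length(reverse) && (any(reverse < 1) || any(reverse > n_items)))
    stop("reverse-coded item indices out of range")
  structure(list(name = name, n_items = n_items,
                 bounds = as.integer(bounds),
                 reverse = as.integer(reverse)),
            class = "scale_definition")
}

#' @rdname scale_definition
#' @export
ngro_definition <- function(reverse = integer(0))
  scale_definition("NGRO", 29L, c(1L, 7L), reverse)

#' @rdname scale_definition
#' @export
asi_bs_definition <- function(reverse = integer(0))
  scale_definition("ASI-BS", 11L, c(0L, 5L), reverse)

#' @rdname scale_definition
#' @export
asi_hs_definition <- function(reverse = integer(0))
  scale_definition("ASI-HS", 11L, c(0L, 5L), reverse)

#' Score a Likert scale
#'
#' Flips reverse-coded items (`min + max - x`), then averages each
#' respondent's answered items. Respondents answering fewer than
#' `min_coverage` of the items are flagged (they are kept in the output so
#' the caller can decide to exclude them).
#'
#' @param responses Integer matrix respondents x items (NA = unanswered),
#'   as produced by [simulate_likert()].
#' @param definition A [scale_definition()].
#' @param min_coverage Minimum fraction of items answered.
#' @return data.table: participant, score, n_answered, flagged.
#' @export
score_scale <- function(responses, definition, min_coverage = 0.8) {
  stopifnot(inherits(definition, "scale_definition"))
  m <- as.matrix(responses)
  if (ncol(m) != definition$n_items)
    stop(definition$name, " expects ", definition$n_items, " items, got ",
         ncol(m))
  oob <- which(!is.na(m) & (m < definition$bounds[1] |
                              m > definition$bounds[2]), arr.ind = TRUE)
  if (nrow(oob))
    stop("out-of-bounds response for participant ", oob[1, 1],
         ", item ", oob[1, 2])
  if (length(definition$reverse))
    m[, definition$reverse] <- definition$bounds[1] + definition$bounds[2] -
      m[, definition$reverse]
  n_answered <- rowSums(!is.na(m))
  data.table::data.table(
    participant = seq_len(nrow(m)),
    score = rowMeans(m, na.rm = TRUE),
    n_answered = n_answered,
    flagged = n_answered < min_coverage * definition$n_items)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))` with
#' n-1-denominator sample variances.
#'
#' @param item_matrix Numeric matrix respondents x items (complete cases
#'   used).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) stop("need at least 2 items")
  if (nrow(m) < 3) stop("need at least 3 respondents")
  vt <- stats::var(rowSums(m))
  if (vt == 0) stop("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' z-standardize a numeric vector
#'
#' `(x - mean) / sd` with the n-1 sample SD; the output has mean 0 and
#' SD 1 and is invariant to affine transformations of the input.
#'
#' @param values Numeric vector, length >= 2, nonzero SD.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero SD: cannot z-standardize")
  (values - mean(values)) / s
}

#' Score all three attitude scales and estimate reliabilities
#'
#' @param ngro,asi_bs,asi_hs Response matrices respondents x items.
#' @param definitions Optional list of three [scale_definition()]s.
#' @return data.table participant, ngro, asi_bs, asi_hs plus z-standardized
#'   columns (`*_z`); Cronbach's alphas attached as attribute `alpha`.
#' @export
score_attitudes <- function(ngro, asi_bs, asi_hs,
                            definitions = list(ngro = ngro_definition(),
                                               asi_bs = asi_bs_definition(),
                                               asi_hs = asi_hs_definition())) {
  out <- data.table::data.table(
    participant = seq_len(nrow(ngro)),
    ngro = score_scale(ngro, definitions$ngro)$score,
    asi_bs = score_scale(asi_bs, definitions$asi_bs)$score,
    asi_hs = score_scale(asi_hs, definitions$asi_hs)$score)
  for (v in c("ngro", "asi_bs", "asi_hs"))
    out[, paste0(v, "_z") := zscore(get(v))]
  data.table::setattr(out, "alpha",
                      c(ngro = cronbach_alpha(ngro),
                        asi_bs = cronbach_alpha(asi_bs),
                        asi_hs = cronbach_alpha(asi_hs)))
  out[]
}
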