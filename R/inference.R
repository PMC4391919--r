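#' Point-wise (PW) detection of credible effects
#'
#' Flags every effect whose marginal posterior sign probability strictly
#' exceeds `alpha`: the proportion of retained draws that are positive (or
#' negative) must exceed the level, which corresponds to a
#' `(1 - 2(1 - alpha))`-level credible interval excluding zero.  Draws
#' exactly equal to zero count toward neither sign.
#'
#' @param effects an `effect_set` from [combined_effect_draws()], or a draws
#'   matrix.
#' @param alpha credibility level in (0.5, 1); the conventional point-wise
#'   level is 0.975.
#' @return a `detection` data frame, one row per effect: `label`, `kind`,
#'   `j`, `k`, `q` (max of the two sign proportions), `sign` (`"+"`/`"-"`),
#'   `credible`.  The level and method are stored as attributes.
#' @export
pw_detect <- function(effects, alpha = 0.975) {
  det <- detection_frame(effects)
  check_level(alpha)
  det$credible <- det$q > alpha
  structure(det, alpha = alpha, method = "pw",
            class = c("detection", "data.frame"))
}

check_level <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0.5 || alpha >= 1)
    stop("credibility level must lie strictly between 0.5 and 1")
  invisible(alpha)
}

as_effect_set <- function(effects) {
  if (inherits(effects, "effect_set")) return(effects)
  combined_effect_draws(as.matrix(effects), NULL)
}

detection_frame <- function(effects) {
  es <- as_effect_set(effects)
  if (nrow(es$draws) < 1L) stop("detection: no posterior draws")
  p_pos <- colMeans(es$draws > 0)
  p_neg <- colMeans(es$draws < 0)
  data.frame(label = es$labels, kind = es$kind, j = es$j, k = es$k,
             q = pmax(p_pos, p_neg),
             sign = ifelse(p_pos >= p_neg, "+", "-"),  # ties resolve to "+"
             credible = FALSE, stringsAsFactors = FALSE)
}

#' Joint posterior sign probability of a selection
#'
#' Fraction of retained draws in which *every* selected effect carries its
#' assigned sign.
#'
#' @param effects an `effect_set` or draws matrix.
#' @param idx integer indices of the selected effect columns (distinct).
#' @param sign character vector of `"+"` / `"-"`, one per selected effect.
#' @return a probability in \[0, 1\].
#' @export
joint_sign_probability <- function(effects, idx, sign) {
  es <- as_effect_set(effects)
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("joint_sign_probability: empty selection")
  if (anyDuplicated(idx)) stop("joint_sign_probability: effects must be distinct")
  if (any(idx < 1L | idx > ncol(es$draws)))
    stop("joint_sign_probability: unknown effect index")
  if (length(sign) != length(idx) || !all(sign %in% c("+", "-")))
    stop("joint_sign_probability: 'sign' must be '+'/'-' matching idx")
  ok <- rep(TRUE, nrow(es$draws))
  for (i in seq_along(idx)) {
    col <- es$draws[, idx[i]]
    ok <- ok & if (sign[i] == "+") col > 0 else col < 0
  }
  mean(ok)
}

#' Simultaneous detection by highest point-wise probabilities (HPW)
#'
#' Greedy simultaneous inference: candidates (single and combined effects)
#' are visited in order of descending marginal sign probability `q` (ties:
#' combined before single, then ascending column index) and added to the
#' selection as long as the *joint* probability that every selected effect
#' carries its sign exceeds `alpha`.  The walk stops at the first
#' non-excluded candidate whose inclusion drops the joint probability to
#' `alpha` or below.
#'
#' Exclusion rules prevent double counting: a single effect is skipped when
#' a selected combined effect already contains its marker, and a combined
#' effect is skipped when either of its markers appears in any selected
#' single or combined effect.
#'
#' @inheritParams pw_detect
#' @param alpha joint credibility level (default 0.95).
#' @return a `detection` data frame as in [pw_detect()]; `credible` flags the
#'   selected effects, and the achieved joint probability is stored in the
#'   `joint_probability` attribute.
#' @export
hpw_select <- function(effects, alpha = 0.95) {
  es <- as_effect_set(effects)
  check_level(alpha)
  det <- detection_frame(es)
  ne <- nrow(det)
  # descending q; ties: combined effects first, then ascending index
  ord <- order(-det$q, det$kind == "single", seq_len(ne))
  selected <- integer(0)
  sel_signs <- character(0)
  used_markers <- integer(0)
  single_selected <- logical(es$m)
  joint <- 1
  for (cand in ord) {
    if (det$kind[cand] == "single") {
      if (det$j[cand] %in% used_markers) next  # inside a selected combined effect
    } else {
      mk <- c(det$j[cand], det$k[cand])
      if (single_selected[det$j[cand]] || single_selected[det$k[cand]]) next
      if (any(mk %in% used_markers)) next
    }
    jp <- joint_sign_probability(es, c(selected, cand),
                                 c(sel_signs, det$sign[cand]))
    if (jp > alpha) {
      selected <- c(selected, cand)
      sel_signs <- c(sel_signs, det$sign[cand])
      joint <- jp
      if (det$kind[cand] == "single") {
        single_selected[det$j[cand]] <- TRUE
      } else {
        used_markers <- c(used_markers, det$j[cand], det$k[cand])
      }
    } else {
      break
    }
  }
  det$credible <- seq_len(ne) %in% selected
  structure(det, alpha = alpha, method = "hpw",
            joint_probability = if (length(selected)) joint else NA_real_,
            class = c("detection", "data.frame"))
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("detection (%s, alpha = %g): %d of %d effects credible\n",
              toupper(attr(x, "method") %||% "?"),
              attr(x, "alpha") %||% NA_real_,
              sum(x$credible %||% logical(0)), nrow(x)))
  cred <- which(x$credible %||% logical(0))
  if (length(cred)) print.data.frame(as.data.frame(x)[cred, ], ...)
  invisible(x)
}

#' Per-locus credibility types
#'
#' Encodes, for every marker locus, how it participates in the credible
#' effects of a detection: `+/-1` when the single effect itself is credible;
#' `+/-0.75` when the locus is the *stronger* member (higher single-effect
#' marginal sign probability) of a credible combined effect of that sign;
#' `+/-0.25` when it is the weaker member; 0 otherwise.  When several
#' conditions hold the largest absolute value wins.  A credibly negative
#' difference `beta_j - beta_k` counts as positive evidence at locus k and
#' negative at locus j (and conversely for a credibly positive difference).
#'
#' @param detection a `detection` from [pw_detect()] or [hpw_select()],
#'   computed over the full effect set (singles plus combined effects).
#' @param m number of marker loci; defaults to the number of single effects
#'   in the detection.
#' @return numeric vector of length `m` with values in
#'   \{0, +/-0.25, +/-0.75, +/-1\}.
#' @export
credibility_types <- function(detection, m = NULL) {
  det <- detection
  singles <- det[det$kind == "single", , drop = FALSE]
  if (is.null(m)) m <- nrow(singles)
  type <- numeric(m)
  q_single <- rep(0.5, m)
  q_single[singles$j] <- singles$q
  assign_type <- function(loc, val) {
    # largest |value| wins; equal magnitude resolves toward the larger value
    if (abs(val) > abs(type[loc]) ||
        (abs(val) == abs(type[loc]) && val > type[loc]))
      type[loc] <<- val
  }
  cred <- det[det$credible, , drop = FALSE]
  if (nrow(cred)) {
    for (i in seq_len(nrow(cred))) {
      s <- if (cred$sign[i] == "+") 1 else -1
      if (cred$kind[i] == "single") {
        assign_type(cred$j[i], s)
      } else {
        jj <- cred$j[i]; kk <- cred$k[i]
        # role signs at each member locus
        sj <- s
        sk <- if (cred$kind[i] == "sum") s else -s
        # strength by the singles' own marginal probabilities; ties favor
        # the lower index as the stronger member
        j_strong <- q_single[jj] >= q_single[kk]
        assign_type(jj, sj * if (j_strong) 0.75 else 0.25)
        assign_type(kk, sk * if (j_strong) 0.25 else 0.75)
      }
    }
  }
  type
}
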