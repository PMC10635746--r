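#' Frame of discernment for the diagnosis problem
#'
#' The evidence is expressed over three focal elements: \{benign\},
#' \{malignant\} and "ignorance". Two readings of ignorance are supported:
#'
#' * `disjoint_singleton` — ignorance is a third, pairwise-disjoint
#'   hypothesis; every cross-class mass product (including those involving
#'   ignorance) is conflicting. Default.
#' * `classical_ds` — ignorance is the whole frame
#'   Theta = \{benign, malignant\}; only benign x malignant products
#'   conflict, and the vacuous mass (0, 0, 1) is the identity of the
#'   combination rule.
#'
#' @param variant `"disjoint_singleton"` or `"classical_ds"`.
#' @return a `ds_frame` object.
#' @export
ds_frame <- function(variant = c("disjoint_singleton", "classical_ds")) {
  variant <- match.arg(variant)
  structure(list(variant = variant, hypotheses = mass_classes()),
            class = "ds_frame")
}

#' Basic probability assignment over benign / malignant / ignorance
#'
#' Masses must be nonnegative and sum to 1; inputs within `1e-9` of unit sum
#' are renormalized exactly, anything further off is rejected.
#'
#' @param benign,malignant,ignorance nonnegative masses.
#' @return a named numeric vector of class `mass_function`.
#' @examples
#' mass_function(0.7, 0.2, 0.1)
#' @export
mass_function <- function(benign, malignant, ignorance) {
  m <- c(benign = benign, malignant = malignant, ignorance = ignorance)
  if (any(!is.finite(m)) || any(m < 0))
    stop("masses must be finite and nonnegative", call. = FALSE)
  s <- sum(m)
  if (s <= 0) stop("masses must not all be zero", call. = FALSE)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("masses sum to %.6g, not 1 (tolerance 1e-9)", s),
         call. = FALSE)
  structure(m / s, class = "mass_function")
}

#' Convert a classifier probability triple to a mass function
#'
#' The mapping is the identity on (p_benign, p_malignant, p_ignorant), with
#' renormalization when the triple does not sum exactly to 1 (no
#' discounting).
#'
#' @param probs numeric length-3 vector (benign, malignant, ignorant), all
#'   entries nonnegative.
#' @return a [mass_function].
#' @examples
#' probs_to_mass(c(0.5, 0.5, 0.2))  # renormalized by 1.2
#' @export
probs_to_mass <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) != 3L)
    stop("`probs` must have length 3", call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("probabilities must be finite and nonnegative", call. = FALSE)
  s <- sum(probs)
  if (s <= 0) stop("probabilities must not all be zero", call. = FALSE)
  probs <- probs / s
  mass_function(probs[1L], probs[2L], probs[3L])
}

as_mass <- function(m) {
  if (inherits(m, "mass_function")) unclass(m) else unclass(probs_to_mass(m))
}

#' Conflict coefficient between two mass functions
#'
#' `k` is the total mass product assigned to pairs of focal elements with
#' empty intersection. Under `disjoint_singleton` every off-diagonal pair
#' conflicts, so `k = 1 - sum_i m1_i m2_i`; under `classical_ds` only the
#' \{benign\} x \{malignant\} cross terms conflict.
#'
#' @param m1,m2 [mass_function]s (or normalizable length-3 vectors).
#' @param frame a [ds_frame].
#' @return the conflict coefficient `k` in `[0, 1]`.
#' @examples
#' ds_conflict(mass_function(0.8, 0.1, 0.1), mass_function(0.6, 0.3, 0.1),
#'             ds_frame("classical_ds"))
#' @export
ds_conflict <- function(m1, m2, frame = ds_frame()) {
  m1 <- as_mass(m1); m2 <- as_mass(m2)
  if (frame$variant == "disjoint_singleton") {
    k <- 1 - sum(m1 * m2)
  } else {
    k <- m1[["benign"]] * m2[["malignant"]] +
      m1[["malignant"]] * m2[["benign"]]
  }
  min(max(k, 0), 1)
}

#' Dempster's rule of combination
#'
#' Combines two mass functions: unnormalized agreement masses are accumulated
#' over focal-element pairs with nonempty intersection and scaled by
#' `K = 1 / (1 - k)` where `k` is the [ds_conflict()] coefficient. Total
#' conflict (`k = 1`) raises an error of class `ds_total_conflict` naming
#' both sources' top classes. The decided label is the argmax of the
#' combined masses; ties are broken by the canonical class order and flagged.
#'
#' @param m1,m2 [mass_function]s (or normalizable length-3 vectors).
#' @param frame a [ds_frame].
#' @return a `ds_fusion_result` list: `mass` (combined [mass_function]),
#'   `k`, `K`, `label`, `tie`.
#' @examples
#' ds_combine(mass_function(0.8, 0.1, 0.1), mass_function(0.6, 0.3, 0.1))
#' @export
ds_combine <- function(m1, m2, frame = ds_frame()) {
  m1 <- as_mass(m1); m2 <- as_mass(m2)
  if (frame$variant == "disjoint_singleton") {
    agree <- m1 * m2  # only identical singletons intersect
  } else {
    b1 <- m1[["benign"]]; g1 <- m1[["malignant"]]; t1 <- m1[["ignorance"]]
    b2 <- m2[["benign"]]; g2 <- m2[["malignant"]]; t2 <- m2[["ignorance"]]
    # ignorance = Theta: B.B, B.Theta, Theta.B -> B; likewise for M;
    # Theta.Theta -> Theta
    agree <- c(benign = b1 * b2 + b1 * t2 + t1 * b2,
               malignant = g1 * g2 + g1 * t2 + t1 * g2,
               ignorance = t1 * t2)
  }
  k <- min(max(1 - sum(agree), 0), 1)
  if (1 - k <= .Machine$double.eps) {
    top <- function(m) mass_classes()[which.max(m)]
    stop(structure(class = c("ds_total_conflict", "error", "condition"),
                   list(message = sprintf(
                     "total conflict (k = 1): sources commit fully to '%s' vs '%s'",
                     top(m1), top(m2)),
                     call = sys.call(-1), m1_top = top(m1), m2_top = top(m2))))
  }
  combined <- agree / sum(agree)
  idx <- which(combined == max(combined))
  structure(list(mass = mass_function(combined[[1L]], combined[[2L]],
                                      combined[[3L]]),
                 k = k, K = 1 / (1 - k),
                 label = mass_classes()[idx[1L]],
                 tie = length(idx) > 1L),
            class = "ds_fusion_result")
}

#' @export
print.ds_fusion_result <- function(x, ...) {
  cat(sprintf(
    "<ds_fusion: m = (%.4f, %.4f, %.4f), k = %.4f, decided = %s%s>\n",
    x$mass[1L], x$mass[2L], x$mass[3L], x$k, x$label,
    if (x$tie) " (tie)" else ""))
  invisible(x)
}

#' Fold Dempster's rule over a list of mass functions
#'
#' Left fold of [ds_combine()]; under `classical_ds` the rule is associative
#' and the result is order-independent.
#'
#' @param masses nonempty list of [mass_function]s.
#' @param frame a [ds_frame].
#' @return a `ds_fusion_result`; for a single mass, that mass with `k = 0`.
#' @export
ds_combine_many <- function(masses, frame = ds_frame()) {
  if (length(masses) < 1L) stop("need at least one mass", call. = FALSE)
  if (length(masses) == 1L) {
    m <- as_mass(masses[[1L]])
    idx <- which.max(m)
    return(structure(list(mass = mass_function(m[[1L]], m[[2L]], m[[3L]]),
                          k = 0, K = 1, label = mass_classes()[idx],
                          tie = FALSE),
                     class = "ds_fusion_result"))
  }
  acc <- masses[[1L]]
  res <- NULL
  for (i in 2L:length(masses)) {
    res <- ds_combine(acc, masses[[i]], frame)
    acc <- res$mass
  }
  res
}

#' Fuse two aligned lists of classifier probability triples
#'
#' Per sample: map each source's triple to a mass function, combine with
#' Dempster's rule, and decide by the maximum combined mass. Samples in
#' total conflict (`k = 1`) cannot be combined; they are flagged and decided
#' by the single source with the higher maximum mass.
#'
#' @param probs1,probs2 `n x 3` matrices (or data frames) of probability
#'   triples, columns in the order [mass_classes()].
#' @param frame a [ds_frame].
#' @return a data frame with columns `sample_id`, `m_benign`, `m_malignant`,
#'   `m_ignorance`, `k`, `decided_label`, `conflict_flag`.
#' @export
fuse_sources <- function(probs1, probs2, frame = ds_frame()) {
  probs1 <- as.matrix(probs1); probs2 <- as.matrix(probs2)
  if (nrow(probs1) != nrow(probs2))
    stop("source lists must have equal length", call. = FALSE)
  n <- nrow(probs1)
  out <- data.frame(sample_id = integer(0), m_benign = numeric(0),
                    m_malignant = numeric(0), m_ignorance = numeric(0),
                    k = numeric(0), decided_label = character(0),
                    conflict_flag = logical(0))
  if (n == 0L) return(out)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m1 <- probs_to_mass(probs1[i, ])
    m2 <- probs_to_mass(probs2[i, ])
    res <- tryCatch(ds_combine(m1, m2, frame),
                    ds_total_conflict = function(e) e)
    if (inherits(res, "ds_total_conflict")) {
      # fall back to the more confident single source
      pick <- if (max(m1) >= max(m2)) m1 else m2
      rows[[i]] <- data.frame(
        sample_id = i, m_benign = pick[[1L]], m_malignant = pick[[2L]],
        m_ignorance = pick[[3L]], k = 1,
        decided_label = mass_classes()[which.max(pick)],
        conflict_flag = TRUE)
    } else {
      rows[[i]] <- data.frame(
        sample_id = i, m_benign = res$mass[[1L]],
        m_malignant = res$mass[[2L]], m_ignorance = res$mass[[3L]],
        k = res$k, decided_label = res$label, conflict_flag = FALSE)
    }
  }
  do.call(rbind, rows)
}
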