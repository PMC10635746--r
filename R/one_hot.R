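#' Diagnostic class labels
#'
#' The fixed, ordered class list used throughout: benign, malignant,
#' ignorant. "Ignorant" is the third class trained on normal (mass-free)
#' images; at fusion time it carries the mass not committed to a specific
#' diagnosis.
#'
#' @return character vector of the three class names, in canonical order.
#' @export
mass_classes <- function() c("benign", "malignant", "ignorant")

#' One-hot encoding of diagnostic labels
#'
#' Encodes labels as 0/1 vectors in the canonical class order
#' (benign = `c(1,0,0)`, malignant = `c(0,1,0)`, ignorant = `c(0,0,1)`);
#' decoding requires exactly one 1 per row.
#'
#' @param labels character or factor vector of class labels.
#' @return `one_hot_encode`: an `n x 3` integer matrix with column names
#'   [mass_classes()].
#' @examples
#' one_hot_encode(c("benign", "ignorant"))
#' one_hot_decode(matrix(c(0, 1, 0), 1))
#' @export
one_hot_encode <- function(labels) {
  labels <- as.character(labels)
  k <- match(labels, mass_classes())
  if (anyNA(k))
    stop("unknown label(s): ",
         paste(unique(labels[is.na(k)]), collapse = ", "), call. = FALSE)
  out <- matrix(0L, length(labels), 3L, dimnames = list(NULL, mass_classes()))
  out[cbind(seq_along(k), k)] <- 1L
  out
}

#' @rdname one_hot_encode
#' @param mat an `n x 3` 0/1 matrix (or a length-3 vector).
#' @return `one_hot_decode`: a character vector of labels.
#' @export
one_hot_decode <- function(mat) {
  if (is.vector(mat)) mat <- matrix(mat, nrow = 1L)
  if (ncol(mat) != 3L)
    stop("one-hot matrix must have 3 columns", call. = FALSE)
  ok <- apply(mat, 1L, function(r) all(r %in% c(0, 1)) && sum(r) == 1)
  if (!all(ok))
    stop("row(s) without exactly one 1 cannot be decoded: ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  mass_classes()[max.col(mat, ties.method = "first")]
}
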