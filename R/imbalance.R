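#' Balance class counts by synthetic minority oversampling (SMOTE)
#'
#' Brings every class up to the size of the largest class by interpolating
#' new rows between existing same-class rows. Each synthetic row is
#' `x + u * (x_nn - x)` where `x` is a minority-class row, `x_nn` one of its
#' `k` nearest same-class neighbours (Euclidean distance on the native
#' feature scale — no standardization), and `u` a single uniform(0, 1) draw
#' applied to the whole row, so every synthetic row lies on the straight
#' segment between two real rows. Original rows are preserved verbatim.
#'
#' @param data A data frame with one numeric feature column set and a class
#'   label column; non-feature metadata columns (character/factor other than
#'   the label) are carried through for real rows and set to `NA` for
#'   synthetic rows.
#' @param label_col Name of the class label column (default `"label"`).
#' @param k Number of nearest same-class neighbours to interpolate towards
#'   (default 5). If `k` exceeds a class's size minus one it is truncated
#'   with a warning.
#' @param seed Optional integer seed making the output reproducible; if
#'   `NULL` the current RNG state is used.
#'
#' @return A tibble with the original rows first, synthetic rows appended,
#'   and a `provenance` column in `{"real", "synthetic_smote"}`.
#' @examples
#' d <- tibble::tibble(f1 = rnorm(12), f2 = rnorm(12),
#'                     label = rep(c("A", "B"), c(8, 4)))
#' table(smote_balance(d, k = 2, seed = 1)$label)
#' @export
smote_balance <- function(data, label_col = "label", k = 5, seed = NULL) {
  if (!label_col %in% names(data)) abort(sprintf("No column `%s`.", label_col))
  if (k < 1) abort("`k` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(data[[label_col]])
  feat_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(feat_cols) == 0L) abort("No numeric feature columns found.")
  if (anyNA(data[feat_cols])) abort("Feature columns contain missing values.")

  counts <- table(labels)
  target <- max(counts)
  out <- as_tibble(data)
  if (!"provenance" %in% names(out)) out$provenance <- "real"

  synth <- list()
  for (cl in names(counts)) {
    n_extra <- target - counts[[cl]]
    if (n_extra == 0) next
    rows <- which(labels == cl)
    if (length(rows) < 2)
      abort(sprintf("Class `%s` has fewer than 2 members; cannot SMOTE.", cl))
    k_cl <- k
    if (k_cl > length(rows) - 1) {
      k_cl <- length(rows) - 1
      warn(sprintf("k truncated to %d for class `%s` (class size %d).",
                   k_cl, cl, length(rows)))
    }
    x <- as.matrix(data[rows, feat_cols])
    dmat <- as.matrix(dist(x))
    diag(dmat) <- Inf
    nn <- apply(dmat, 1, function(d) order(d)[seq_len(k_cl)], simplify = FALSE)
    if (is.matrix(nn)) nn <- asplit(nn, 2) # k_cl == 1 edge shapes

    # deal generation duties round-robin over the minority rows, then pick
    # the neighbour and gap at random for each synthetic row
    base <- rep(seq_along(rows), length.out = n_extra)
    pick <- vapply(base, function(b) nn[[b]][sample.int(k_cl, 1)], integer(1))
    u <- runif(n_extra)
    newx <- x[base, , drop = FALSE] + u * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])

    srow <- as_tibble(as.data.frame(newx))
    srow[[label_col]] <- cl
    srow$provenance <- "synthetic_smote"
    synth[[cl]] <- srow
  }
  if (length(synth)) out <- dplyr::bind_rows(out, dplyr::bind_rows(synth))
  out
}
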