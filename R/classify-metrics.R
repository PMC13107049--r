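#' Stratified train/test split
#'
#' Splits a labeled cell table into disjoint train and test subsets at
#' the requested fraction within every population (rounding toward the
#' training side, while always leaving at least one test cell per
#' population).
#'
#' @param table data.frame with a label column.
#' @param train_fraction fraction of each population assigned to
#'   training, in (0, 1).
#' @param label_col name of the label column.
#' @param seed integer seed; the same seed reproduces the partition
#'   exactly.
#' @return A list with elements `train` and `test`.
#' @export
stratified_split <- function(table, train_fraction = 0.8,
                             label_col = "population", seed = NULL) {
  stopifnot(is.data.frame(table), label_col %in% names(table),
            train_fraction > 0, train_fraction < 1)
  lab <- as.character(table[[label_col]])
  counts <- table(lab)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop("populations with fewer than 2 cells: ",
         paste(small, collapse = ", "))
  with_seed(seed, {
    train_idx <- unlist(lapply(split(seq_len(nrow(table)), lab), function(ix) {
      n_train <- min(ceiling(train_fraction * length(ix)), length(ix) - 1L)
      sample(ix, n_train)
    }), use.names = FALSE)
    list(train = table[sort(train_idx), , drop = FALSE],
         test = table[-sort(train_idx), , drop = FALSE])
  })
}

#' Confusion matrix and classification accuracy
#'
#' Tallies predictions against true labels. The confusion matrix is
#' row-normalized (rows = true populations, columns = predictions, each
#' row summing to 1). Overall accuracy is pooled per-cell correctness;
#' the macro average of per-class accuracies is also reported.
#'
#' @param true,predicted equal-length label vectors.
#' @param labels label universe (defaults to the union observed); a
#'   predicted label outside it is an error.
#' @return A list: `confusion` (row-normalized), `counts` (raw),
#'   `accuracy` (pooled), `macro_accuracy`, `per_class`.
#' @export
confusion_accuracy <- function(true, predicted, labels = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("label vectors differ in length")
  if (is.null(labels)) labels <- sort(unique(c(true, predicted)))
  bad <- setdiff(unique(c(true, predicted)), labels)
  if (length(bad)) stop("labels outside the model set: ",
                        paste(bad, collapse = ", "))
  tf <- factor(true, levels = labels)
  pf <- factor(predicted, levels = labels)
  counts <- table(true = tf, predicted = pf)
  rs <- rowSums(counts)
  conf <- counts / ifelse(rs == 0, 1, rs)
  per_class <- diag(counts) / ifelse(rs == 0, NA, rs)
  list(confusion = conf, counts = counts,
       accuracy = mean(true == predicted),
       macro_accuracy = mean(per_class, na.rm = TRUE),
       per_class = per_class)
}

#' Classification sensitivity
#'
#' True positives over ground-truth positives, as a percentage — the
#' metric used for dye-validated classification checks.
#'
#' @param true_positive,ground_truth nonnegative counts with
#'   `true_positive <= ground_truth` and `ground_truth > 0`.
#' @return Percentage in \[0, 100\].
#' @examples
#' sensitivity(19, 20)  # 95
#' @export
sensitivity <- function(true_positive, ground_truth) {
  stopifnot(length(true_positive) == 1L, length(ground_truth) == 1L)
  if (ground_truth <= 0) stop("ground_truth must be positive")
  if (true_positive < 0 || true_positive > ground_truth)
    stop("true_positive must lie in [0, ground_truth]")
  100 * true_positive / ground_truth
}

#' Unsupervised k-means classification with cluster merging
#'
#' Partitions the feature space into `n_clusters` k-means clusters and
#' maps every cluster to the reference population holding the majority
#' of its members. The mapping is many-to-one, so a population whose
#' cells split across two clusters (e.g. a bimodally distributed tag)
#' has both clusters merged back onto it — which is why `n_clusters`
#' may exceed the number of populations.
#'
#' @param features numeric matrix or data.frame of feature columns.
#' @param n_clusters number of k-means clusters (>= number of reference
#'   populations).
#' @param reference_labels true population per row, used for the
#'   majority-vote remap and accuracy.
#' @param seed integer seed for the k-means initialization.
#' @param nstart random restarts passed to [stats::kmeans()].
#' @param max_retry re-seeding attempts if a cluster comes back empty.
#' @return A list: `predicted` (remapped labels), `cluster` (raw
#'   cluster index per cell), `mapping` (cluster -> population),
#'   `accuracy` (pooled), `confusion` (row-normalized).
#' @export
kmeans_classify <- function(features, n_clusters, reference_labels,
                            seed = NULL, nstart = 10, max_retry = 3) {
  X <- as.matrix(features)
  ref <- as.character(reference_labels)
  stopifnot(nrow(X) == length(ref))
  n_pop <- length(unique(ref))
  if (n_clusters < n_pop)
    stop("n_clusters must be at least the number of reference populations")
  km <- NULL
  with_seed(seed, {
    for (attempt in seq_len(max_retry)) {
      km <- suppressWarnings(kmeans(X, centers = n_clusters, nstart = nstart))
      if (all(km$size > 0)) break
      km <- NULL
    }
  })
  if (is.null(km)) stop("k-means produced an empty cluster after ",
                        max_retry, " attempts")
  mapping <- vapply(seq_len(n_clusters), function(cl) {
    members <- ref[km$cluster == cl]
    names(which.max(table(members)))
  }, character(1))
  predicted <- mapping[km$cluster]
  ca <- confusion_accuracy(ref, predicted, labels = sort(unique(ref)))
  list(predicted = predicted, cluster = km$cluster, mapping = mapping,
       accuracy = ca$accuracy, confusion = ca$confusion)
}
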