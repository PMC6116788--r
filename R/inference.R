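#' Tag excitatory neurons with the classes that drove them during training
#'
#' Each neuron with nonzero total training spikes receives its top
#' `n_tags` classes by cumulative training spike count (ties broken toward
#' the lower class index). Neurons that never spiked during training are
#' untagged and excluded from the group sizes.
#'
#' @param class_counts Matrix of cumulative training spike counts,
#'   neurons x classes.
#' @param n_tags Tags per neuron: 1 (image-like) or 2 (speech-like).
#' @return An object of class `tag_assignment`: `tags` (list of integer
#'   class vectors, empty for untagged neurons), `group_sizes` (per-class
#'   number of neurons carrying the tag), `n_classes`, `n_tags`.
#' @export
tag_neurons <- function(class_counts, n_tags = 1) {
  stopifnot(is.matrix(class_counts), all(class_counts >= 0),
            n_tags >= 1, ncol(class_counts) >= n_tags)
  n_classes <- ncol(class_counts)
  tags <- apply(class_counts, 1, function(cnt) {
    if (sum(cnt) == 0) return(integer(0))
    order(cnt, decreasing = TRUE)[seq_len(n_tags)]  # order() ties -> lower index
  }, simplify = FALSE)
  group_sizes <- tabulate(unlist(tags), nbins = n_classes)
  structure(
    list(tags = tags, group_sizes = group_sizes,
         n_classes = n_classes, n_tags = as.integer(n_tags)),
    class = "tag_assignment"
  )
}

#' Per-class average spike count of the tagged neuron groups
#'
#' For each class `j` with `n_j > 0` tagged neurons, the mean test-phase
#' spike count of those neurons; classes with no tagged neurons get 0. A
#' neuron carrying several tags contributes its full spike count to every
#' group it belongs to.
#'
#' @param spike_count Per-neuron spike counts for one test presentation
#'   (vector of length `n_e`), or a [present_pattern()] `record`.
#' @param tags A [tag_neurons()] result.
#' @return Named numeric vector of per-class average spike counts.
#' @export
average_spike_count <- function(spike_count, tags) {
  if (inherits(spike_count, "spike_record")) spike_count <- spike_count$spike_count
  stopifnot(inherits(tags, "tag_assignment"),
            length(spike_count) == length(tags$tags))
  sums <- numeric(tags$n_classes)
  for (k in seq_along(tags$tags)) {
    for (j in tags$tags[[k]]) sums[j] <- sums[j] + spike_count[k]
  }
  avg <- ifelse(tags$group_sizes > 0, sums / pmax(tags$group_sizes, 1), 0)
  stats::setNames(avg, seq_len(tags$n_classes))
}

#' Predict the class from per-class average spike counts (single liquid)
#'
#' Argmax over classes; ties are broken deterministically toward the
#' lowest class index (with a warning).
#'
#' @param avg Per-class average spike counts.
#' @return Predicted class index (integer).
#' @export
predict_single <- function(avg) {
  if (length(avg) == 0) stop("no classes to predict from", call. = FALSE)
  top <- which(avg == max(avg))
  if (length(top) > 1) {
    warning("tie in average spike counts; predicting the lowest class index",
            call. = FALSE)
  }
  as.integer(top[1])
}

#' Combine per-liquid averages and predict the class (ensemble)
#'
#' The resultant per-class average spike count is the mean over liquids of
#' the per-liquid averages (a liquid with no neurons tagged `j`
#' contributes 0 while the divisor stays `n_liquids`); the prediction is
#' its argmax with the same tie rule as [predict_single()]. With one
#' liquid this reduces exactly to the single-liquid prediction.
#'
#' @param per_liquid_avg List of per-class average spike count vectors, one
#'   per liquid, over a common class set.
#' @return An object of class `prediction_result`: `avg_spike_count` (the
#'   per-liquid inputs), `res_avg_spike_count`, `predicted_class`.
#' @export
predict_ensemble <- function(per_liquid_avg) {
  stopifnot(length(per_liquid_avg) >= 1)
  n_classes <- length(per_liquid_avg[[1]])
  if (!all(vapply(per_liquid_avg, length, 0L) == n_classes)) {
    stop("liquids report inconsistent class sets", call. = FALSE)
  }
  res <- Reduce(`+`, per_liquid_avg) / length(per_liquid_avg)
  structure(
    list(avg_spike_count = per_liquid_avg,
         res_avg_spike_count = res,
         predicted_class = predict_single(res)),
    class = "prediction_result"
  )
}

#' Confusion matrix and per-class false-negative / false-positive rates
#'
#' The confusion matrix has rows indexed by predicted class and columns by
#' actual class. False negatives of class `j` are its column sum minus the
#' diagonal entry, as a percentage of the test samples of class `j`.
#' False positives of predicted class `j` are its row sum minus the
#' diagonal, as a percentage of the test samples not of class `j`.
#'
#' @param actual,predicted Integer class labels (1-based) of equal length.
#' @param n_classes Number of classes.
#' @return A list: `confusion` (`n_classes` x `n_classes` matrix,
#'   predicted x actual), `accuracy` (percent), `fn_pct`, `fp_pct`
#'   (per-class percentages; `NaN` where the denominator is zero).
#' @export
confusion_and_rates <- function(actual, predicted, n_classes) {
  stopifnot(length(actual) == length(predicted),
            all(actual >= 1), all(actual <= n_classes),
            all(predicted >= 1), all(predicted <= n_classes))
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(predicted = seq_len(n_classes),
                               actual = seq_len(n_classes)))
  for (s in seq_along(actual)) {
    cm[predicted[s], actual[s]] <- cm[predicted[s], actual[s]] + 1L
  }
  diag_cm <- diag(cm)
  per_class_n <- colSums(cm)
  fn <- (per_class_n - diag_cm) / per_class_n * 100
  fp <- (rowSums(cm) - diag_cm) / (sum(cm) - per_class_n) * 100
  list(confusion = cm,
       accuracy = sum(diag_cm) / length(actual) * 100,
       fn_pct = as.numeric(fn),
       fp_pct = as.numeric(fp))
}
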