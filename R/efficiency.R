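#' Efficiency input for one model
#'
#' Bundles the quantities the efficiency scores are computed from: the
#' trainable-parameter count and the number of epochs needed to reach minimum
#' validation loss (their product is the cost `k`), plus the test accuracy and
#' loss to be normalized.
#'
#' @param model_id Character label.
#' @param trainable_params Positive integer.
#' @param epochs_to_min_val_loss Positive integer.
#' @param accuracy_percent Test accuracy in `[0, 100]`.
#' @param loss Non-negative test loss.
#' @return An object of class `efficiency_input`.
#' @export
efficiency_input <- function(model_id, trainable_params,
                             epochs_to_min_val_loss, accuracy_percent, loss) {
  trainable_params <- assert_count(trainable_params, "trainable_params")
  epochs_to_min_val_loss <- assert_count(epochs_to_min_val_loss,
                                         "epochs_to_min_val_loss")
  stopifnot(accuracy_percent >= 0, accuracy_percent <= 100, loss >= 0)
  structure(list(model_id = as.character(model_id),
                 trainable_params = trainable_params,
                 epochs_to_min_val_loss = epochs_to_min_val_loss,
                 accuracy_percent = as.numeric(accuracy_percent),
                 loss = as.numeric(loss),
                 k = as.numeric(trainable_params) * epochs_to_min_val_loss),
            class = "efficiency_input")
}

#' Efficiency factor
#'
#' `f = log10(k_target) / min_m log10(k_m)` over a cohort of compared models,
#' where `k = trainable parameters x epochs to minimum validation loss`. The
#' cohort minimizer gets `f = 1`; every other model `f > 1`. A score is only
#' meaningful within its cohort, which is therefore an explicit argument.
#'
#' @param target An [efficiency_input()]; must be a member of `cohort`.
#' @param cohort List of [efficiency_input()]s.
#' @return Numeric `f >= 1`.
#' @examples
#' a <- efficiency_input("small", 1e5, 1, 84, 0.5)
#' b <- efficiency_input("large", 1e7, 1, 84, 0.5)
#' efficiency_factor(b, list(a, b))  # 1.4
#' @export
efficiency_factor <- function(target, cohort) {
  stopifnot(inherits(target, "efficiency_input"))
  ks <- vapply(cohort, function(m) {
    stopifnot(inherits(m, "efficiency_input"))
    m$k
  }, numeric(1))
  if (!any(vapply(cohort, function(m) identical(m, target), logical(1)))) {
    stop("`target` must be a member of `cohort`", call. = FALSE)
  }
  if (any(ks <= 1)) {
    stop("degenerate cost: every cohort member needs k > 1", call. = FALSE)
  }
  log10(target$k) / min(log10(ks))
}

#' Accuracy and loss efficiency scores
#'
#' `aes = accuracy / f` (stays in `[0, 100]`) and `les = loss * f`
#' (stays in `[0, Inf)`). Models with many parameters and slow convergence get
#' lower accuracy efficiency and higher loss efficiency scores.
#'
#' @param input An [efficiency_input()].
#' @param f Efficiency factor from [efficiency_factor()]; must be `>= 1`.
#' @return List with `aes` and `les`.
#' @export
efficiency_scores <- function(input, f) {
  stopifnot(inherits(input, "efficiency_input"))
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 1) {
    stop("`f` must be a single number >= 1", call. = FALSE)
  }
  list(aes = input$accuracy_percent / f, les = input$loss * f)
}

#' Efficiency report for a cohort of models
#'
#' Computes `k`, the efficiency factor and both scores for every member of a
#' cohort and returns them as one table (exportable with
#' [utils::write.csv()]).
#'
#' @param cohort List of [efficiency_input()]s.
#' @return `data.frame` with columns `model_id, params, epochs, k, f,
#'   accuracy, aes, loss, les`.
#' @export
efficiency_report <- function(cohort) {
  rows <- lapply(cohort, function(m) {
    f <- efficiency_factor(m, cohort)
    sc <- efficiency_scores(m, f)
    data.frame(model_id = m$model_id, params = m$trainable_params,
               epochs = m$epochs_to_min_val_loss, k = m$k, f = f,
               accuracy = m$accuracy_percent, aes = sc$aes,
               loss = m$loss, les = sc$les)
  })
  do.call(rbind, rows)
}
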