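#' Paired input/output dataset for one group and one mapping direction
#'
#' Holds the concatenated (input, output) PU pairs of every subject in one
#' group, for one mapping direction, with subject boundaries recorded so
#' that downstream lagging never crosses subjects.
#'
#' @param input,output Numeric vectors of strictly positive PU values,
#'   equal length; `input[k]` and `output[k]` are the two sides of the same
#'   frame.
#' @param subject Subject label per pair; pairs of one subject must be
#'   contiguous, and all subject blocks must have equal length.
#' @param group Group label (`"A"`, `"B"`, `"C"`).
#' @param direction Mapping direction, `"L->R"` or `"R->L"` (which side is
#'   designated the model input).
#' @return An object of class `group_dataset`.
#' @export
group_dataset <- function(input, output, subject, group, direction = c("L->R", "R->L")) {
  direction <- match.arg(direction)
  n <- length(input)
  if (length(output) != n || length(subject) != n)
    stop_structural("input, output and subject must have equal length")
  if (n == 0L) stop_structural("a group dataset cannot be empty")
  if (any(!is.finite(input)) || any(!is.finite(output)) ||
      any(input <= 0) || any(output <= 0))
    stop_positivity("all PU values in a group dataset must be positive and finite")
  subject <- as.character(subject)
  r <- rle(subject)
  if (anyDuplicated(r$values))
    stop_structural("pairs of one subject must be contiguous")
  if (length(unique(r$lengths)) > 1L)
    stop_structural("subject blocks must all have the same length")
  structure(
    list(input = as.numeric(input), output = as.numeric(output),
         subject = subject, group = as.character(group), direction = direction),
    class = "group_dataset")
}

#' @export
print.group_dataset <- function(x, ...) {
  ns <- length(unique(x$subject))
  cat(sprintf("Group dataset: group %s, direction %s, %d pairs (%d subjects x %d)\n",
              x$group, x$direction, length(x$input), ns, length(x$input) / ns))
  invisible(x)
}

#' Swap the input/output designation of a dataset
#'
#' Returns the same pairs with the mapping direction reversed, for the
#' reverse analysis that checks whether cross-side amplification depends on
#' which side was designated the model input.
#'
#' @param dataset A [group_dataset()].
#' @return A `group_dataset` with input and output exchanged.
#' @export
reverse_direction <- function(dataset) {
  stopifnot(inherits(dataset, "group_dataset"))
  group_dataset(dataset$output, dataset$input, dataset$subject, dataset$group,
                if (dataset$direction == "L->R") "R->L" else "L->R")
}
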