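clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate all unordered crosses of a set of inbred parents
#'
#' @param parents Character vector of parent ids.
#' @return Data frame with columns `hybrid`, `parent1`, `parent2`, one row per
#'   unordered pair (n * (n - 1) / 2 rows; 66 for 12 parents).
#' @export
diallel_crosses <- function(parents) {
  parents <- as.character(parents)
  if (anyDuplicated(parents)) stop("duplicated parent ids")
  idx <- utils::combn(length(parents), 2)
  data.frame(hybrid = paste(parents[idx[1, ]], parents[idx[2, ]], sep = "x"),
             parent1 = parents[idx[1, ]], parent2 = parents[idx[2, ]],
             stringsAsFactors = FALSE)
}
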