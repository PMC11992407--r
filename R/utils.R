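#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm rexp rbinom rgamma rnbinom rlnorm median sd
#' @importFrom utils head
NULL

# round-half-up: calibrated zero counts must not depend on banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' Derive a per-task seed from a master seed and a label path
#'
#' Deterministic polynomial hash of the master seed plus any number of
#' labels (dataset id, corruption kind, level, run index, ...), reduced
#' modulo 2^31 - 1 so the result is always a valid R integer seed. Used by
#' the sweep orchestration so every (kind, level, run, algorithm) cell of a
#' grid gets a reproducible, collision-resistant seed.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the task.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "dropout_expression", 0.5, 3)
derive_seed <- function(master, ...) {
  parts <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                 collapse = "")
  h <- 7
  for (b in utf8ToInt(parts)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

check_count_matrix <- function(x, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric cells x genes matrix", arg))
  }
  if (nrow(x) == 0L || ncol(x) == 0L) {
    abort(sprintf("`%s` must be non-empty", arg))
  }
  if (anyNA(x)) abort(sprintf("`%s` contains missing values", arg))
  if (min(x) < 0) abort(sprintf("`%s` contains negative entries", arg))
  invisible(x)
}

is_integer_valued <- function(x) {
  all(abs(x - round(x)) < sqrt(.Machine$double.eps))
}

# Accept an annotation as a tibble (cell_id, type_label) or a named vector;
# return a character vector of labels aligned to `cell_ids`.
align_annotation <- function(annotation, cell_ids) {
  if (is.data.frame(annotation)) {
    if (!all(c("cell_id", "type_label") %in% names(annotation))) {
      abort("annotation must have columns `cell_id` and `type_label`")
    }
    lab <- as.character(annotation$type_label)
    names(lab) <- as.character(annotation$cell_id)
  } else {
    lab <- as.character(annotation)
    names(lab) <- names(annotation)
  }
  if (is.null(names(lab)) || !all(cell_ids %in% names(lab))) {
    abort("annotation does not cover every cell in the matrix")
  }
  unname(lab[cell_ids])
}
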