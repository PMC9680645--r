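#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   bind_rows distinct n left_join across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd var qf pf pt qtukey ptukey rpois rgamma rlnorm rbinom
#'   quantile rnorm rexp runif complete.cases
NULL

SEVERITY_LEVELS <- c("none", "mild", "moderate", "severe")
ACCOUNT_LEVELS <- c("checking", "credit")

# evaluate `expr` under a temporary RNG seed, restoring global RNG state
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

severity_factor <- function(x) {
  x <- as.character(x)
  bad <- !(x %in% SEVERITY_LEVELS)
  if (any(bad)) {
    abort(sprintf("invalid severity value(s): %s",
                  paste(unique(x[bad]), collapse = ", ")))
  }
  factor(x, levels = SEVERITY_LEVELS)
}

month_floor <- function(d) lubridate::floor_date(d, "month")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
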