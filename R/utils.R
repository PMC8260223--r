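#' @keywords internal
"_PACKAGE"

#' @importFrom stats optimize optim p.adjust pchisq rbinom rexp rgamma
#'   rlnorm rmultinom rnbinom rnorm rpois runif t.test var setNames
#' @importFrom utils read.delim
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Tab-separated writer used by every table output: UTF-8, newline-terminated,
# no quoting, no row names.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else format(v, scientific = FALSE, trim = TRUE, digits = 15)
      }, character(1))
      out
    } else as.character(x)
  }
  header <- paste(names(df), collapse = "\t")
  body <- do.call(paste, c(lapply(df, fmt), sep = "\t"))
  writeLines(c(header, body), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
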