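# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed annotation tables use the
#' conventional half-up rule (0.025 -> 0.03 at two decimals), so percentage
#' columns are rounded with this helper instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.025, 2)   # 0.03
#' round_half_up(78.4540, 2) # 78.45
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # tiny epsilon guards against representation error in x * p (e.g. 1.005 * 100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Largest-remainder apportionment: integer counts summing to n with
# proportions as close to `props` as possible. Deterministic.
apportion <- function(n, props) {
  stopifnot(n >= 0, all(props >= 0))
  props <- props / sum(props)
  raw <- n * props
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[take] <- counts[take] + 1
  }
  stats::setNames(as.integer(counts), names(props))
}

# Strip AUGUSTUS-style transcript suffixes (".t1", ".t12") so protein ids can
# be matched against gene/mRNA feature ids.
normalize_feature_id <- function(id) {
  sub("\\.t[0-9]+$", "", id)
}

# Read a tab-separated file into a character matrix, keeping empty trailing
# fields, skipping blank and '#' comment lines. Returns list(fields, lineno).
read_tab_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE), lineno = lineno[keep])
}

# Parse numeric fields with a line-numbered error on failure.
as_numeric_checked <- function(x, what, lineno, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("%s: non-numeric %s field on line %d ('%s')",
                 basename(path), what, lineno[bad][1], x[bad][1]), call. = FALSE)
  }
  out
}

# Append a timestamped line to the run log (no-op when log is NULL).
log_line <- function(log, fmt, ...) {
  if (is.null(log)) return(invisible(NULL))
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              sprintf(fmt, ...)), file = log, append = TRUE)
  invisible(NULL)
}
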