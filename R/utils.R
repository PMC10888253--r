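#' Normalize a marker name
#'
#' Marker identity must survive changes of reagent, fluorochrome and channel
#' order, so all marker comparisons go through a single normalization:
#' uppercase, Greek letters transliterated, punctuation and spaces stripped,
#' then an alias table (e.g. `"CD279"` is PD1, `"TCR alpha beta"` is TCRAB).
#'
#' @param x character vector of marker names as found in panel configs or
#'   FCS `$PnS` keywords.
#' @return character vector of normalized names.
#' @examples
#' normalize_marker(c("CD279 (PD1)", "TCR αβ", "IgD"))
#' @export
normalize_marker <- function(x) {
  y <- toupper(as.character(x))
  y <- gsub("α|Α", "A", y)
  y <- gsub("β|Β", "B", y)
  y <- gsub("γ|Γ", "G", y)
  y <- gsub("δ|Δ", "D", y)
  y <- gsub("ALPHA", "A", y)
  y <- gsub("BETA", "B", y)
  y <- gsub("GAMMA", "G", y)
  y <- gsub("DELTA", "D", y)
  y <- gsub("[^A-Z0-9]", "", y)
  aliases <- c(
    "CD279" = "PD1", "CD279PD1" = "PD1",
    "TCRA" = "TCRAB", "TCRG" = "TCRGD",
    "HLADR" = "HLADR", "IGD" = "IGD",
    "KAPPA" = "KAPPA", "LAMBDA" = "LAMBDA"
  )
  hit <- !is.na(aliases[y])
  y[hit] <- aliases[y[hit]]
  y
}

# Scatter/time detector names recognized as non-fluorescence channels.
.cg_scatter_names <- c("FSCA", "FSCH", "SSCA", "SSCH", "TIME")

.is_scatter_or_time <- function(names) {
  gsub("[^A-Z0-9]", "", toupper(names)) %in% .cg_scatter_names
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483629L)
}

cg_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "cg_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Canonical JSON used for all reports: fixed key order (construction order),
# full numeric precision, so that identical inputs give identical bytes.
cg_write_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null", pretty = TRUE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

cg_read_json <- function(path) {
  jsonlite::fromJSON(readLines(path, warn = FALSE),
                     simplifyVector = FALSE)
}
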