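# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats runif rpois rbinom setNames optimize ppois
#' @importFrom utils read.delim write.table head modifyList
NULL

## Case-fold + trim a surface form (gene symbol, synonym, locus tag).
normSurface <- function(x) {
  x <- trimws(as.character(x))
  tolower(x)
}

## Product-name normalization: case-fold, collapse internal whitespace.
normProduct <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

## Split a gene symbol into (family, subunit qualifier).  The qualifier is a
## single trailing capital letter on a lower-case stem (dsrA -> dsr + A);
## locus-tag-like symbols (dde_2265) have no qualifier.
symbolFamily <- function(symbol) {
  s <- trimws(as.character(symbol))
  has_qual <- grepl("^[A-Za-z]{2,}[A-Z]$", s)
  fam <- ifelse(has_qual, substr(s, 1L, nchar(s) - 1L), s)
  tolower(fam)
}

symbolQualifier <- function(symbol) {
  s <- trimws(as.character(symbol))
  has_qual <- grepl("^[A-Za-z]{2,}[A-Z]$", s)
  ifelse(has_qual, substr(s, nchar(s), nchar(s)), "")
}

## Numerically stable log(sum(exp(x))) over matrix rows.
logRowSumExp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## Derive an independent 31-bit sub-seed from a master seed for a named
## stream, so each generator draws from its own reproducible stream.
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

## Half-up rounding to `digits` decimals (reports print 69.83-style figures;
## base round() is banker's rounding).
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## The six pathway labels used throughout the workflow.
pathwayLevels <- function() {
  c("sulfur metabolism", "ribosome synthesis", "nucleotide metabolism",
    "transporters", "energy metabolism", "two-component system")
}

partitionLevels <- function() c("persistent", "shell", "cloud")
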