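# Dictionary construction and TSV IO ("Microbe annotator" dictionary stage).

#' Build a gene dictionary from annotation records
#'
#' Turns a per-gene annotation table into a [GeneDictionary-class]: the
#' surface-form lookup contains the case-normalized primary symbol, every
#' synonym, and the locus tag itself.  A normalized surface form claimed by
#' two different locus tags is an ambiguity and aborts the build with a
#' message listing the collisions.
#'
#' @param records \code{data.frame} with columns \code{locus_tag},
#'   \code{symbol}, and optionally \code{synonyms} (\code{|}-separated),
#'   \code{product}, \code{pathway}, \code{go_terms}
#'   (\code{;}-separated \code{GO:NNNNNNN:A}, aspect \code{A} in
#'   \code{F}/\code{P}/\code{C}).
#' @return A [GeneDictionary-class] object.
#' @examples
#' d <- buildGeneDictionary(data.frame(
#'   locus_tag = c("dde_0526", "dde_2265"),
#'   symbol = c("dsrA", "sat"),
#'   synonyms = c("dsvA", ""),
#'   product = c("Sulfite reductase alpha", "Sulfate adenylyltransferase"),
#'   pathway = "sulfur metabolism",
#'   go_terms = c("GO:0018551:F", "GO:0004781:F")))
#' surfaceLookup(d)[["dsva"]]
#' @export
buildGeneDictionary <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopIfNot(nrow(records) == 0 || all(c("locus_tag", "symbol") %in% names(records)),
            "records must have at least locus_tag and symbol columns")
  for (col in c("synonyms", "product", "pathway", "go_terms"))
    if (is.null(records[[col]])) records[[col]] <- rep("", nrow(records))
  records[is.na(records)] <- ""
  if (anyDuplicated(records$locus_tag))
    stop("duplicate locus tags: ",
         paste(unique(records$locus_tag[duplicated(records$locus_tag)]),
               collapse = ", "), call. = FALSE)

  if (nrow(records) == 0) {
    return(new("GeneDictionary",
               records = data.frame(locus_tag = character(), symbol = character(),
                                    synonyms = character(), product = character(),
                                    pathway = character(), go_terms = character(),
                                    stringsAsFactors = FALSE),
               lookup = setNames(character(), character())))
  }

  surfaces <- lapply(seq_len(nrow(records)), function(i) {
    syn <- strsplit(records$synonyms[i], "|", fixed = TRUE)[[1]]
    syn <- syn[nzchar(trimws(syn))]
    unique(normSurface(c(records$symbol[i], syn, records$locus_tag[i])))
  })
  lookup <- setNames(rep(records$locus_tag, lengths(surfaces)),
                     unlist(surfaces))
  # same surface repeated for one gene is fine; for two genes it is ambiguous
  dup <- duplicated(cbind(names(lookup), lookup))
  lookup <- lookup[!dup]
  coll <- names(lookup)[duplicated(names(lookup))]
  if (length(coll)) {
    detail <- vapply(unique(coll), function(s)
      paste0("'", s, "' -> ", paste(lookup[names(lookup) == s], collapse = ", ")),
      character(1))
    stop("ambiguous surface forms:\n  ", paste(detail, collapse = "\n  "),
         call. = FALSE)
  }
  new("GeneDictionary", records = records[, c("locus_tag", "symbol", "synonyms",
                                              "product", "pathway", "go_terms")],
      lookup = lookup)
}

#' Read / write a gene dictionary TSV
#'
#' The TSV dialect has columns \code{locus_tag}, \code{symbol},
#' \code{synonyms}, \code{product}, \code{pathway}, \code{go_terms}.
#'
#' @param path file path.
#' @param dictionary a [GeneDictionary-class].
#' @return \code{readGeneDictionary} returns a [GeneDictionary-class];
#'   \code{writeGeneDictionary} returns \code{path} invisibly.
#' @export
readGeneDictionary <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  buildGeneDictionary(tab)
}

#' @rdname readGeneDictionary
#' @export
writeGeneDictionary <- function(dictionary, path) {
  stopifnot(is(dictionary, "GeneDictionary"))
  utils::write.table(geneRecords(dictionary), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Parse ";"-separated "GO:NNNNNNN:A" entries into a data.frame(go_id, aspect).
parseGoTerms <- function(go_terms) {
  out <- lapply(strsplit(as.character(go_terms), ";", fixed = TRUE), function(v) {
    v <- trimws(v[nzchar(trimws(v))])
    if (!length(v)) return(data.frame(go_id = character(), aspect = character()))
    parts <- regmatches(v, regexec("^(GO:\\d{7}):?([FPC]?)$", v))
    bad <- vapply(parts, length, 1L) == 0L | !vapply(parts, function(p) nzchar(p[2]), TRUE)
    if (any(bad))
      stop("malformed GO term: ", paste(v[bad], collapse = ", "), call. = FALSE)
    data.frame(go_id = vapply(parts, `[`, "", 2L),
               aspect = vapply(parts, `[`, "", 3L),
               stringsAsFactors = FALSE)
  })
  out
}
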