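# Segregation of per-gene partitions by pathway, essentiality calls and the
# presence/absence heatmap export.

#' Segregate genes by pathway and pangenome partition
#'
#' Cross-tabulates genes into a pathway x (persistent, shell, cloud) count
#' table with row totals, a grand-totals row, and per-partition percentages
#' of the grand total (rounded half-up to 2 decimals; recomputed from the
#' counts, never cached).  Genes without a pathway fall under
#' \code{"uncategorized"}; an unknown partition label is an error.
#'
#' @param gene_partitions \code{data.frame} with columns \code{gene},
#'   \code{partition} and optionally \code{pathway} (a named pathway map for
#'   the genes may be supplied separately).
#' @param pathway optional named character vector gene -> pathway, overriding
#'   the \code{pathway} column.
#' @return A list with \code{table} (\code{data.frame}: pathway, persistent,
#'   shell, cloud, total; last row \code{TOTAL}), \code{percentages} (named
#'   numeric over partitions) and \code{total} genes.
#' @examples
#' seg <- segregatePartitions(loadFixtures()$partitions)
#' seg$percentages
#' @export
segregatePartitions <- function(gene_partitions, pathway = NULL) {
  gp <- as.data.frame(gene_partitions, stringsAsFactors = FALSE)
  if (!nrow(gp)) {
    tab <- data.frame(pathway = "TOTAL", persistent = 0L, shell = 0L,
                      cloud = 0L, total = 0L)
    return(list(table = tab,
                percentages = setNames(rep(NA_real_, 3), partitionLevels()),
                total = 0L))
  }
  stopIfNot(all(c("gene", "partition") %in% names(gp)),
            "gene_partitions needs gene and partition columns")
  bad <- !gp$partition %in% partitionLevels()
  if (any(bad))
    stop("unknown partition label for gene(s): ",
         paste(gp$gene[bad], collapse = ", "), call. = FALSE)
  pw <- if (!is.null(pathway)) unname(pathway[gp$gene]) else gp$pathway
  if (is.null(pw)) pw <- rep(NA_character_, nrow(gp))
  pw[is.na(pw) | !nzchar(trimws(pw))] <- "uncategorized"
  lev <- c(intersect(pathwayLevels(), pw), setdiff(sort(unique(pw)),
                                                   pathwayLevels()))
  ct <- table(factor(pw, levels = lev),
              factor(gp$partition, levels = partitionLevels()))
  tab <- data.frame(pathway = rownames(ct), persistent = ct[, "persistent"],
                    shell = ct[, "shell"], cloud = ct[, "cloud"],
                    total = rowSums(ct), row.names = NULL,
                    stringsAsFactors = FALSE)
  tab <- rbind(tab, data.frame(pathway = "TOTAL",
                               persistent = sum(tab$persistent),
                               shell = sum(tab$shell),
                               cloud = sum(tab$cloud),
                               total = sum(tab$total)))
  grand <- tab$total[tab$pathway == "TOTAL"]
  pct <- setNames(roundHalfUp(100 *
    unlist(tab[tab$pathway == "TOTAL", partitionLevels()]) / grand, 2L),
    partitionLevels())
  list(table = tab, percentages = pct, total = as.integer(grand))
}

#' Call gene essentiality from pangenome partitions
#'
#' Deterministic mapping: a \code{persistent} gene is called
#' \code{essential}, a \code{shell} gene \code{conditionally-essential}, a
#' \code{cloud} gene \code{environment-specific} — persistent families are
#' near-universally conserved across the genus, while shell and cloud
#' membership tracks ecological conditions.  Per-gene overrides (e.g., a
#' shell gene whose essentiality depends on formate as electron donor) add a
#' rationale note from the supplied config; an override naming an absent
#' gene raises a warning.
#'
#' @param gene_partitions \code{data.frame} with \code{gene},
#'   \code{partition}, optional \code{pathway}.
#' @param overrides optional named character vector gene -> note.
#' @return \code{data.frame} with \code{gene}, \code{pathway},
#'   \code{partition}, \code{call}, \code{note}.
#' @export
callEssentiality <- function(gene_partitions, overrides = NULL) {
  gp <- as.data.frame(gene_partitions, stringsAsFactors = FALSE)
  call_map <- c(persistent = "essential", shell = "conditionally-essential",
                cloud = "environment-specific")
  bad <- !gp$partition %in% names(call_map)
  if (any(bad))
    stop("unknown partition label for gene(s): ",
         paste(gp$gene[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(gene = gp$gene,
                    pathway = if (is.null(gp$pathway))
                      rep("uncategorized", nrow(gp)) else gp$pathway,
                    partition = gp$partition,
                    call = unname(call_map[gp$partition]),
                    note = rep("", nrow(gp)), stringsAsFactors = FALSE)
  if (!is.null(overrides) && length(overrides)) {
    absent <- setdiff(names(overrides), out$gene)
    if (length(absent))
      warning("override(s) name absent gene(s): ",
              paste(absent, collapse = ", "))
    hit <- intersect(names(overrides), out$gene)
    out$note[match(hit, out$gene)] <- unname(overrides[hit])
  }
  out
}

#' Ordered presence/absence export for heatmap display
#'
#' Extracts the requested families and orders rows by (partition, presence
#' frequency) — persistent rows first, then shell, then cloud, each block in
#' decreasing frequency — and columns by decreasing genome fill.  The result
#' round-trips bit-exactly through CSV.
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param families subset of families to export (default: all).
#' @param partition optional named character vector family -> partition used
#'   for the primary ordering.
#' @param image optional path; when given and \pkg{pheatmap} is installed, a
#'   rendered heatmap is written there.
#' @return The ordered binary matrix (invisibly also written to \code{path}
#'   if supplied via \code{csv}).
#' @param csv optional CSV output path.
#' @export
heatmapMatrix <- function(pa, families = NULL, partition = NULL, csv = NULL,
                          image = NULL) {
  stopifnot(is(pa, "PresenceAbsenceMatrix"))
  m <- paMatrix(pa)
  if (is.null(families)) families <- rownames(m)
  unknown <- setdiff(families, rownames(m))
  if (length(unknown))
    stop("unknown families: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m <- m[families, , drop = FALSE]
  freq <- rowMeans(m)
  if (!is.null(partition)) {
    pr <- match(partition[rownames(m)], partitionLevels())
    pr[is.na(pr)] <- length(partitionLevels()) + 1L
  } else pr <- rep(1L, nrow(m))
  m <- m[order(pr, -freq, rownames(m)), , drop = FALSE]
  m <- m[, order(-colMeans(m), colnames(m)), drop = FALSE]
  if (!is.null(csv)) utils::write.csv(m, csv, quote = FALSE)
  if (!is.null(image)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                         color = c("white", "darkgreen"), legend = FALSE,
                         filename = image)
    } else warning("pheatmap not installed; image not rendered")
  }
  m
}

#' Write the segregation report
#'
#' Writes the segregation table as CSV, the essentiality calls as TSV, and a
#' combined JSON + Markdown report.
#'
#' @param segregation result of [segregatePartitions()].
#' @param calls result of [callEssentiality()].
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeReport <- function(segregation, calls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(segregation = file.path(dir, "segregation.csv"),
             calls = file.path(dir, "essentiality_calls.tsv"),
             json = file.path(dir, "report.json"),
             md = file.path(dir, "report.md"))
  utils::write.csv(segregation$table, paths[["segregation"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.table(calls, paths[["calls"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(segregation = segregation$table,
                            percentages = as.list(segregation$percentages),
                            total = segregation$total,
                            calls = calls),
                       paths[["json"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  md <- c("# Essentiality segregation report", "",
          sprintf("Total genes: %d", segregation$total),
          sprintf("Persistent: %s%%, shell: %s%%, cloud: %s%%",
                  segregation$percentages[["persistent"]],
                  segregation$percentages[["shell"]],
                  segregation$percentages[["cloud"]]), "",
          "| pathway | persistent | shell | cloud | total |",
          "|---|---|---|---|---|",
          sprintf("| %s | %d | %d | %d | %d |",
                  segregation$table$pathway, segregation$table$persistent,
                  segregation$table$shell, segregation$table$cloud,
                  segregation$table$total))
  writeLines(md, paths[["md"]])
  invisible(paths)
}
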