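# Mention-level evaluation of a recognizer against gold annotations.

prfCounts <- function(tp, fp, fn) {
  # 0/0 precision and recall are defined as 0 (penalizes empty predictions)
  p <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

matchCounts <- function(gold, pred) {
  key <- function(m) paste(m$doc_id, m$start, m$end, m$locus_tag, sep = "\r")
  gk <- key(gold); pk <- key(pred)
  # each gold mention matches at most one prediction (keys are exact spans,
  # duplicates on either side consume matches one-for-one)
  tp <- 0L
  gt <- table(gk)
  pt <- table(pk)
  common <- intersect(names(gt), names(pt))
  for (k in common) tp <- tp + min(gt[[k]], pt[[k]])
  c(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

#' Exact-span mention evaluation
#'
#' A predicted mention is a true positive iff a gold mention with identical
#' (doc_id, start, end, locus tag) exists; matching is one-to-one.  No
#' partial credit is given.  Precision and recall use the 0/0 = 0
#' convention; F1 is their harmonic mean.
#'
#' @param gold,predicted [AnnotatedCorpus-class] objects over the same
#'   document ids.
#' @return An [EvalResult-class].
#' @examples
#' d <- loadFixtures()$dictionary
#' g <- annotateDocument("x", "dsrA binds sat", d)
#' evalScores(evaluateMentions(g, g))[["f1"]]
#' @export
evaluateMentions <- function(gold, predicted) {
  stopifnot(is(gold, "AnnotatedCorpus"), is(predicted, "AnnotatedCorpus"))
  gd <- sort(documents(gold)$doc_id)
  pd <- sort(documents(predicted)$doc_id)
  if (!identical(gd, pd))
    stop("gold and predicted corpora cover different doc_ids", call. = FALSE)
  n <- matchCounts(mentions(gold), mentions(predicted))
  s <- prfCounts(n[["tp"]], n[["fp"]], n[["fn"]])
  new("EvalResult", tp = n[["tp"]], fp = n[["fp"]], fn = n[["fn"]],
      precision = s$precision, recall = s$recall, f1 = s$f1,
      slices = data.frame(), mean_f1 = s$f1, best_f1 = s$f1)
}

#' Slice-based evaluation with mean and best F1
#'
#' Documents are partitioned into \code{n_slices} near-equal slices by a
#' seed-determined shuffle of the sorted document ids (so the result does not
#' depend on input document order), each slice is scored by
#' [evaluateMentions()], and the per-slice F1 scores are summarized by their
#' mean ("average F1") and maximum ("best F1") alongside the pooled
#' corpus-level counts.
#'
#' @inheritParams evaluateMentions
#' @param n_slices number of slices, \code{1 <= n_slices <=} number of
#'   documents.
#' @param seed integer seed for the document shuffle.
#' @return An [EvalResult-class] with per-slice scores.
#' @export
sliceEvaluate <- function(gold, predicted, n_slices, seed = 1L) {
  stopifnot(is(gold, "AnnotatedCorpus"), is(predicted, "AnnotatedCorpus"))
  ids <- sort(documents(gold)$doc_id)
  stopIfNot(n_slices >= 1, "n_slices must be >= 1")
  stopIfNot(n_slices <= length(ids),
            "n_slices must not exceed the number of documents")
  pooled <- evaluateMentions(gold, predicted)

  set.seed(deriveSeed(seed, "slice-eval"))
  shuffled <- sample(ids)
  assignment <- rep(seq_len(n_slices), length.out = length(ids))
  gm <- mentions(gold); pm <- mentions(predicted)
  rows <- lapply(seq_len(n_slices), function(s) {
    docs <- shuffled[assignment == s]
    n <- matchCounts(gm[gm$doc_id %in% docs, , drop = FALSE],
                     pm[pm$doc_id %in% docs, , drop = FALSE])
    sc <- prfCounts(n[["tp"]], n[["fp"]], n[["fn"]])
    data.frame(slice = s, n_docs = length(docs), tp = n[["tp"]],
               fp = n[["fp"]], fn = n[["fn"]], precision = sc$precision,
               recall = sc$recall, f1 = sc$f1)
  })
  slices <- do.call(rbind, rows)
  new("EvalResult", tp = pooled@tp, fp = pooled@fp, fn = pooled@fn,
      precision = pooled@precision, recall = pooled@recall, f1 = pooled@f1,
      slices = slices, mean_f1 = mean(slices$f1), best_f1 = max(slices$f1))
}

#' Write an evaluation report as JSON
#'
#' @param result an [EvalResult-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(result, path) {
  stopifnot(is(result, "EvalResult"))
  obj <- as.list(evalScores(result))
  if (nrow(sliceScores(result))) obj$slices <- sliceScores(result)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
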