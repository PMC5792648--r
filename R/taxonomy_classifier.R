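WORD_MODEL_VERSION <- "rrnabias-wordmodel-1"

# distinct overlapping w-mers of a sequence as base-4 integer ids; windows
# containing non-ACGT characters are skipped
distinct_words <- function(s, w) {
  unique(kmer_ids(s, w))
}

#' Train the naive Bayes k-mer word model
#'
#' Builds the genus-conditional word statistics used for taxonomic
#' assignment: with `N` training sequences of which `n(word)` contain a
#' word, the word prior is `p(word) = (n(word) + 0.5) / (N + 1)`, and for a
#' genus `G` with `M_G` sequences of which `m_G(word)` contain the word, the
#' conditional is `p(word | G) = (m_G(word) + p(word)) / (M_G + 1)`.
#'
#' @param refset a `ReferenceSet` (its sequences and genus labels form the
#'   training set), or a list with elements `seqs` (named character vector)
#'   and `taxa` (data.frame with `taxon_id` and the six rank columns).
#' @param w word size (8 by default).
#' @return object of class `WordModel`: word size, `N`, genus table
#'   (`genus`, `M` and the genus lineage), the per-word prior and the dense
#'   log-conditional matrix (`4^w` rows, one column per genus, columns in
#'   lexicographic genus order).
#' @export
train_classifier <- function(refset, w = 8L) {
  seqs <- refset$seqs
  taxa <- refset$taxa
  stop_if_not(length(seqs) >= 1, "empty training set")
  stop_if_not(all(nchar(seqs) >= w), "every training sequence must have length >= w")
  genera <- sort(unique(taxa$genus))
  G <- length(genera)
  nwords <- 4L^w
  n_word <- integer(nwords)
  m <- matrix(0L, nrow = nwords, ncol = G, dimnames = list(NULL, genera))
  gidx <- match(taxa$genus, genera)
  for (i in seq_along(seqs)) {
    ids <- distinct_words(seqs[[i]], w) + 1L
    n_word[ids] <- n_word[ids] + 1L
    m[ids, gidx[i]] <- m[ids, gidx[i]] + 1L
  }
  N <- length(seqs)
  M <- as.integer(table(factor(taxa$genus, levels = genera)))
  prior <- (n_word + 0.5) / (N + 1)
  logp <- log((m + prior) / rep(M + 1, each = nwords))
  lin <- taxa[match(genera, taxa$genus), RANKS, drop = FALSE]
  rownames(lin) <- NULL
  structure(list(version = WORD_MODEL_VERSION, w = as.integer(w), N = N,
                 genera = genera, M = M, prior = prior, logp = logp,
                 lineage = lin),
            class = "WordModel")
}

#' @export
print.WordModel <- function(x, ...) {
  cat(sprintf("WordModel (%s): w=%d, N=%d sequences, %d genera\n",
              x$version, x$w, x$N, length(x$genera)))
  invisible(x)
}

#' Query word probabilities from a model
#'
#' @param model a `WordModel`.
#' @param word a w-mer string over A,C,G,T.
#' @param genus optional genus label; when given, returns `p(word | genus)`,
#'   otherwise the word prior.
#' @return a probability.
#' @export
word_probability <- function(model, word, genus = NULL) {
  stop_if_not(nchar(word) == model$w, "word length must equal model word size")
  id <- kmer_ids(word, model$w) + 1L
  stop_if_not(length(id) == 1L, "word must be over A,C,G,T")
  if (is.null(genus)) return(unname(model$prior[id]))
  j <- match(genus, model$genera)
  stop_if_not(!is.na(j), "unknown genus")
  unname(exp(model$logp[id, j]))
}

#' Save / load a word model
#'
#' Serialises the model (with its embedded version string) to a single
#' binary archive.
#'
#' @param model a `WordModel`.
#' @param path file path.
#' @return `path` invisibly / the restored model.
#' @export
write_word_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_word_model
#' @export
read_word_model <- function(path) {
  model <- readRDS(path)
  stop_if_not(identical(model$version, WORD_MODEL_VERSION),
              "unrecognised word model version")
  model
}

# common-prefix depth matrix between all genus pairs (G x G)
lineage_depth_matrix <- function(lin) {
  G <- nrow(lin)
  lm <- as.matrix(lin)
  D <- matrix(0L, G, G)
  for (r in seq_len(6L)) {
    eq <- outer(lm[, r], lm[, r], "==")
    # depth advances only while all shallower ranks agree
    D <- D + (D == (r - 1L)) * eq
  }
  D
}

#' Classify reads with the naive Bayes word model
#'
#' For each read, the distinct overlapping w-mers are scored against every
#' genus (`score(G) = sum of log p(word | G)`); both strands are evaluated
#' and the strand with the higher best score is kept. Confidence comes from
#' bootstrap resampling: `n_bootstrap` draws of one eighth of the read's
#' distinct words (with replacement) are each assigned to their best genus,
#' and the support of a rank is the fraction of draws whose winning genus
#' shares the read's best lineage down to that rank. The assigned lineage is
#' truncated at the first rank whose support falls below `threshold`.
#'
#' @param sequences character vector of reads (each at least `w` long).
#' @param model a `WordModel`.
#' @param n_bootstrap number of bootstrap draws.
#' @param threshold support threshold for the assigned lineage (0.8 default;
#'   0.5 replicates the relaxed mode).
#' @param seed integer seed for the bootstrap.
#' @param read_ids optional read identifiers.
#' @return data.frame with `read_id`, `strand`, `score`, one label column
#'   per rank (`domain`..`genus`, NA where support is below threshold) and
#'   one support column per rank (`domain_support`..`genus_support`).
#' @export
classify_reads <- function(sequences, model, n_bootstrap = 100L,
                           threshold = 0.8, seed = 1,
                           read_ids = NULL) {
  stop_if_not(all(nchar(sequences) >= model$w),
              "every sequence must have length >= the model word size")
  n <- length(sequences)
  if (is.null(read_ids)) read_ids <- sprintf("read_%d", seq_len(n))
  G <- length(model$genera)
  logp <- model$logp

  words_f <- lapply(sequences, distinct_words, w = model$w)
  words_r <- lapply(rev_comp(sequences), distinct_words, w = model$w)
  score_of <- function(words) {
    X <- Matrix::sparseMatrix(i = rep.int(seq_len(n), lengths(words)),
                              j = unlist(words, use.names = FALSE) + 1L,
                              x = 1, dims = c(n, 4L^model$w))
    as.matrix(X %*% logp)
  }
  sf <- score_of(words_f)
  sr <- score_of(words_r)
  best_f <- sf[cbind(seq_len(n), max.col(sf, "first"))]
  best_r <- sr[cbind(seq_len(n), max.col(sr, "first"))]
  use_f <- best_f >= best_r
  scores <- sf; scores[!use_f, ] <- sr[!use_f, ]
  words <- words_f; words[!use_f] <- words_r[!use_f]
  best <- max.col(scores, "first")
  best_score <- scores[cbind(seq_len(n), best)]

  # bootstrap: draws of |V|/8 words with replacement, scored per genus
  D <- lineage_depth_matrix(model$lineage)
  lens <- lengths(words)
  nw <- pmax(1L, lens %/% 8L)
  allw <- unlist(words, use.names = FALSE)
  off <- cumsum(c(0L, lens[-n]))
  ridx <- rep.int(seq_len(n), nw)
  agree <- matrix(0L, n, 6L)
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      pick <- off[ridx] + pmax(1L, ceiling(runif(length(ridx)) * lens[ridx]))
      Xb <- Matrix::sparseMatrix(i = ridx, j = allw[pick] + 1L, x = 1,
                                 dims = c(n, 4L^model$w))
      gb <- max.col(as.matrix(Xb %*% logp), "first")
      depth <- D[cbind(gb, best)]
      for (r in seq_len(6L)) agree[, r] <- agree[, r] + (depth >= r)
    }
  })
  support <- agree / n_bootstrap

  labels <- as.matrix(model$lineage)[best, , drop = FALSE]
  assigned_depth <- apply(support >= threshold, 1L, function(x) {
    bad <- which(!x)
    if (length(bad) == 0L) 6L else bad[1L] - 1L
  })
  for (r in seq_len(6L)) labels[assigned_depth < r, r] <- NA_character_
  out <- data.frame(read_id = read_ids,
                    strand = ifelse(use_f, "+", "-"),
                    score = best_score,
                    best_genus = model$genera[best],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(labels, stringsAsFactors = FALSE))
  colnames(support) <- paste0(RANKS, "_support")
  cbind(out, as.data.frame(support))
}

#' Classify a single sequence
#'
#' @inheritParams classify_reads
#' @param sequence a single read.
#' @return object of class `ClassificationResult`: list with
#'   `best_lineage`, `support` (named, domain to genus), `assigned` (labels,
#'   NA below threshold), `strand`, `threshold`.
#' @export
classify <- function(sequence, model, n_bootstrap = 100L, threshold = 0.8,
                     seed = 1) {
  stop_if_not(nchar(sequence) >= model$w,
              "sequence shorter than the model word size")
  row <- classify_reads(sequence, model, n_bootstrap, threshold, seed)
  support <- setNames(as.numeric(row[1, paste0(RANKS, "_support")]), RANKS)
  assigned <- setNames(as.character(row[1, RANKS]), RANKS)
  best <- as.character(model$lineage[match(row$best_genus, model$genera), ])
  structure(list(best_lineage = setNames(best, RANKS), support = support,
                 assigned = assigned, strand = row$strand,
                 threshold = threshold),
            class = "ClassificationResult")
}

#' @export
print.ClassificationResult <- function(x, ...) {
  d <- sum(!is.na(x$assigned))
  cat(sprintf("ClassificationResult: assigned to %s (depth %d, strand %s)\n",
              if (d > 0) x$assigned[d] else "<root>", d, x$strand))
  invisible(x)
}

#' Concordance merge of forward and reverse assignments
#'
#' Combines two independent mate classifications by keeping the deepest
#' ("lowest") taxonomic prefix on which the assigned lineages agree. When
#' one mate is unclassifiable (no rank assigned), the other mate's
#' assignment is returned and flagged.
#'
#' @param resultF,resultR `ClassificationResult` objects, or named character
#'   vectors of assigned labels (domain to genus, NA below the assignment).
#' @return list with `assigned` (named labels, NA below the concordant
#'   depth), `depth` and `fallback` (TRUE when one mate was unclassified).
#' @export
concordance_merge <- function(resultF, resultR) {
  a <- if (is(resultF, "ClassificationResult")) resultF$assigned else resultF
  b <- if (is(resultR, "ClassificationResult")) resultR$assigned else resultR
  stop_if_not(length(a) == 6L && length(b) == 6L,
              "assignments must cover the six-rank ladder")
  da <- sum(!is.na(a)); db <- sum(!is.na(b))
  if (da == 0L || db == 0L) {
    pick <- if (da == 0L) b else a
    return(list(assigned = pick, depth = max(da, db), fallback = TRUE))
  }
  d <- common_prefix_depth(a, b)
  out <- a
  if (d < 6L) out[(d + 1L):6L] <- NA_character_
  list(assigned = out, depth = d, fallback = FALSE)
}

#' Per-rank concordance between two classification tables
#'
#' Reports, for each rank, the fraction of read pairs whose two mates carry
#' the same (non-missing) label -- the statistic used to judge whether
#' merging mates before classification matters.
#'
#' @param tableF,tableR data.frames from [classify_reads()], row-aligned by
#'   pair.
#' @return data.frame with `rank`, `n_both_assigned`, `concordant`,
#'   `fraction`.
#' @export
concordance_table <- function(tableF, tableR) {
  stop_if_not(nrow(tableF) == nrow(tableR), "tables must be row-aligned")
  do.call(rbind, lapply(RANKS, function(r) {
    fa <- tableF[[r]]; ra <- tableR[[r]]
    both <- !is.na(fa) & !is.na(ra)
    conc <- sum(both & fa == ra, na.rm = TRUE)
    data.frame(rank = r, n_both_assigned = sum(both), concordant = conc,
               fraction = if (sum(both) > 0) conc / sum(both) else NA_real_)
  }))
}

#' Concordance-merge two classification tables
#'
#' Applies [concordance_merge()] to every row pair and returns a
#' classification-style table of merged assignments.
#'
#' @inheritParams concordance_table
#' @return data.frame with `read_id`, the six rank columns and `fallback`.
#' @export
concordance_merge_table <- function(tableF, tableR) {
  stop_if_not(nrow(tableF) == nrow(tableR), "tables must be row-aligned")
  n <- nrow(tableF)
  lab <- matrix(NA_character_, n, 6L, dimnames = list(NULL, RANKS))
  fb <- logical(n)
  for (i in seq_len(n)) {
    m <- concordance_merge(setNames(as.character(tableF[i, RANKS]), RANKS),
                           setNames(as.character(tableR[i, RANKS]), RANKS))
    lab[i, ] <- m$assigned
    fb[i] <- m$fallback
  }
  cbind(data.frame(read_id = tableF$read_id, stringsAsFactors = FALSE),
        as.data.frame(lab, stringsAsFactors = FALSE),
        data.frame(fallback = fb))
}

#' Leave-one-out genus recovery
#'
#' Classifier validation on a reference set with at least two strains per
#' genus: one strain per genus is held out of training, random fragments of
#' the held-out sequence are classified against the reduced model, and
#' recovery records whether the assigned lineage reaches the correct genus.
#'
#' @param refset a `ReferenceSet` built with `strains_per_genus >= 2`.
#' @param fragment_len fragment length drawn from the held-out sequence.
#' @param n_fragments fragments classified per held-out strain.
#' @param w,n_bootstrap,threshold classifier settings.
#' @param seed integer seed (fragment positions and bootstrap).
#' @return data.frame with `taxon_id`, `genus`, `recovered` (all fragments
#'   assigned to the true genus) and `support_monotone`.
#' @export
loo_genus_recovery <- function(refset, fragment_len = 250, n_fragments = 1L,
                               w = 8L, n_bootstrap = 100L, threshold = 0.8,
                               seed = 1) {
  taxa <- refset$taxa
  genera <- unique(taxa$genus)
  multi <- vapply(genera, function(g) sum(taxa$genus == g) >= 2L, logical(1L))
  stop_if_not(all(multi), "every genus needs at least 2 strains for leave-one-out")
  held <- vapply(genera, function(g) taxa$taxon_id[taxa$genus == g][1L],
                 character(1L))
  with_seed(seed, {
    res <- lapply(seq_along(genera), function(i) {
      out_id <- held[i]
      train <- subset_reference_set(refset, setdiff(taxa$taxon_id, out_id))
      model <- train_classifier(train, w)
      s <- refset$seqs[[out_id]]
      starts <- sample.int(nchar(s) - fragment_len + 1L, n_fragments,
                           replace = TRUE)
      frags <- substring(s, starts, starts + fragment_len - 1L)
      cl <- classify_reads(frags, model, n_bootstrap, threshold,
                           seed = sample.int(.Machine$integer.max, 1L))
      sup <- as.matrix(cl[, paste0(RANKS, "_support")])
      data.frame(taxon_id = out_id, genus = genera[i],
                 recovered = all(!is.na(cl$genus) & cl$genus == genera[i]),
                 support_monotone = all(apply(sup, 1L, function(x)
                   all(diff(x) <= 1e-12))))
    })
    do.call(rbind, res)
  })
}

#' Restrict a reference set to a subset of taxa
#'
#' Used to emulate alternative (e.g. incomplete) training databases.
#'
#' @param refset a `ReferenceSet`.
#' @param taxon_ids taxa to keep.
#' @return a `ReferenceSet` containing only those taxa.
#' @export
subset_reference_set <- function(refset, taxon_ids) {
  keep <- refset$taxa$taxon_id %in% taxon_ids
  stop_if_not(any(keep), "subset would be empty")
  out <- refset
  out$taxa <- refset$taxa[keep, , drop = FALSE]
  rownames(out$taxa) <- NULL
  out$seqs <- refset$seqs[refset$taxa$taxon_id[keep]]
  out
}
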