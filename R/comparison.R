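#' Uniform subsample of classified reads
#'
#' @param classifications data.frame of per-read rows.
#' @param n number of rows to draw (without replacement).
#' @param seed integer seed.
#' @return data.frame with `n` rows (original order preserved).
#' @export
subsample <- function(classifications, n, seed = 1) {
  total <- nrow(classifications)
  stop_if_not(n <= total, "subsample size exceeds the number of reads")
  if (n == total) return(classifications)
  sel <- with_seed(seed, sort(sample.int(total, n)))
  classifications[sel, , drop = FALSE]
}

#' Build an abundance table at a rank
#'
#' Counts reads per taxon at the requested rank; reads unassigned at that
#' rank are tallied separately and excluded from the relative fractions.
#'
#' @param classifications data.frame with the six rank columns (from
#'   [classify_reads()], a truth table joined to lineages, or a concordance
#'   merge).
#' @param rank taxonomic rank.
#' @param sample_id,method optional labels stored as attributes.
#' @return data.frame of class `abundance_table` with `taxon`, `count`,
#'   `fraction`; attributes `rank`, `sample_id`, `method`, `unassigned`,
#'   `total`.
#' @export
abundance_table <- function(classifications, rank, sample_id = NA_character_,
                            method = NA_character_) {
  stop_if_not(rank %in% RANKS, "unknown rank")
  lab <- classifications[[rank]]
  tab <- table(lab[!is.na(lab)])
  out <- data.frame(taxon = names(tab), count = as.integer(tab),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out$fraction <- if (sum(out$count) > 0) out$count / sum(out$count) else 0
  structure(out, class = c("abundance_table", "data.frame"), rank = rank,
            sample_id = sample_id, method = method,
            unassigned = sum(is.na(lab)), total = length(lab))
}

#' Log2 abundance ratios between two methods
#'
#' Per taxon in the union of the two tables:
#' `log2((countA + pseudocount) / totalA) - log2((countB + pseudocount) /
#' totalB)`. The pseudocount keeps ratios finite for taxa absent from one
#' method (swapping the tables negates every ratio).
#'
#' @param tableA,tableB `abundance_table` objects at the same rank.
#' @param pseudocount added to each count (0.5 by default).
#' @return data.frame with `taxon`, `log2_ratio`, `count_a`, `count_b`.
#' @export
log2_ratio_table <- function(tableA, tableB, pseudocount = 0.5) {
  stop_if_not(identical(attr(tableA, "rank"), attr(tableB, "rank")),
              "tables must be at the same rank")
  taxa <- sort(union(tableA$taxon, tableB$taxon))
  ca <- tableA$count[match(taxa, tableA$taxon)]; ca[is.na(ca)] <- 0L
  cb <- tableB$count[match(taxa, tableB$taxon)]; cb[is.na(cb)] <- 0L
  ta <- sum(tableA$count); tb <- sum(tableB$count)
  data.frame(taxon = taxa,
             log2_ratio = log2((ca + pseudocount) / ta) -
               log2((cb + pseudocount) / tb),
             count_a = ca, count_b = cb,
             stringsAsFactors = FALSE)
}

#' Squared Pearson correlation between two abundance tables
#'
#' Computed on linear relative fractions over the union of taxa (absent
#' taxa count as 0). With fewer than 3 shared taxa or a zero-variance
#' vector the statistic is undefined and NA is returned with a warning.
#'
#' @inheritParams log2_ratio_table
#' @return squared Pearson correlation in `[0, 1]`, or NA.
#' @export
r_squared <- function(tableA, tableB) {
  stop_if_not(identical(attr(tableA, "rank"), attr(tableB, "rank")),
              "tables must be at the same rank")
  shared <- intersect(tableA$taxon, tableB$taxon)
  if (length(shared) < 3L) {
    warning("fewer than 3 shared taxa; r_squared undefined")
    return(NA_real_)
  }
  taxa <- sort(union(tableA$taxon, tableB$taxon))
  fa <- tableA$fraction[match(taxa, tableA$taxon)]; fa[is.na(fa)] <- 0
  fb <- tableB$fraction[match(taxa, tableB$taxon)]; fb[is.na(fb)] <- 0
  if (sd(fa) == 0 || sd(fb) == 0) {
    warning("zero variance; r_squared undefined")
    return(NA_real_)
  }
  cor(fa, fb)^2
}

#' Differential abundance between two conditions
#'
#' For each taxon, per-replicate relative fractions are compared between
#' conditions with a two-sided unequal-variance (Welch) t-test; the fold
#' change is the ratio of pseudocounted mean fractions, reported as an
#' x-fold increase or decrease. Taxa absent from one condition keep a
#' finite fold through the pseudocount and are flagged.
#'
#' @param before,after lists of `abundance_table` objects (the replicate
#'   tables of each condition; at least 2 each).
#' @param rank taxonomic rank (must match the tables).
#' @param pseudocount added to counts when computing fold changes.
#' @return data.frame with `taxon`, `mean_before`, `mean_after`, `fold`,
#'   `direction` (`"increase"`/`"decrease"`/`"none"`), `p_value`,
#'   `absent_flag`.
#' @export
differential_abundance <- function(before, after, rank, pseudocount = 0.5) {
  stop_if_not(length(before) >= 2 && length(after) >= 2,
              "need at least 2 replicates per condition")
  all_tabs <- c(before, after)
  stop_if_not(all(vapply(all_tabs, function(t)
    identical(attr(t, "rank"), rank), logical(1L))),
    "all tables must be at the requested rank")
  taxa <- sort(unique(unlist(lapply(all_tabs, `[[`, "taxon"))))
  frac_mat <- function(tabs, pc = 0) {
    vapply(tabs, function(t) {
      cc <- t$count[match(taxa, t$taxon)]; cc[is.na(cc)] <- 0L
      (cc + pc) / sum(t$count)
    }, numeric(length(taxa)))
  }
  fb <- frac_mat(before); fa <- frac_mat(after)
  fbp <- frac_mat(before, pseudocount); fap <- frac_mat(after, pseudocount)
  if (length(taxa) == 1L) {
    fb <- matrix(fb, 1L); fa <- matrix(fa, 1L)
    fbp <- matrix(fbp, 1L); fap <- matrix(fap, 1L)
  }
  res <- lapply(seq_along(taxa), function(i) {
    mb <- mean(fbp[i, ]); ma <- mean(fap[i, ])
    fold <- if (ma >= mb) ma / mb else mb / ma
    dir <- if (ma > mb) "increase" else if (ma < mb) "decrease" else "none"
    p <- tryCatch(t.test(fb[i, ], fa[i, ], var.equal = FALSE)$p.value,
                  error = function(e) {
                    if (isTRUE(all.equal(mean(fb[i, ]), mean(fa[i, ])))) 1 else 0
                  })
    data.frame(taxon = taxa[i], mean_before = mean(fb[i, ]),
               mean_after = mean(fa[i, ]), fold = fold, direction = dir,
               p_value = p,
               absent_flag = all(fb[i, ] == 0) || all(fa[i, ] == 0))
  })
  do.call(rbind, res)
}

#' Mean 16S copy number per taxonomic group
#'
#' @param refset a `ReferenceSet`.
#' @param rank grouping rank.
#' @return data.frame with `taxon`, `n_taxa`, `mean_copy_number`.
#' @export
mean_copy_number_by_taxon <- function(refset, rank) {
  stop_if_not(rank %in% RANKS, "unknown rank")
  grp <- refset$taxa[[rank]]
  agg <- aggregate(list(mean_copy_number = refset$taxa$copy_number),
                   by = list(taxon = grp), FUN = mean)
  cnt <- aggregate(list(n_taxa = rep(1L, nrow(refset$taxa))),
                   by = list(taxon = grp), FUN = sum)
  merge(cnt, agg, by = "taxon")
}

#' Truth-based per-read assignments
#'
#' Joins a simulator output (or its truth table) to the reference lineages,
#' yielding the same per-read rank columns that [classify_reads()] produces
#' -- the error-free "oracle classifier" used to isolate sampling biases
#' from classification noise. Background reads get NA at every rank.
#'
#' @param pairs data.frame with a `taxon_id` column (simulator output).
#' @param refset a `ReferenceSet`.
#' @return data.frame with `read_id` (if present) and the six rank columns.
#' @export
truth_assignments <- function(pairs, refset) {
  idx <- match(pairs$taxon_id, refset$taxa$taxon_id)
  out <- refset$taxa[idx, RANKS, drop = FALSE]
  rownames(out) <- NULL
  if ("read_id" %in% names(pairs))
    out <- cbind(data.frame(read_id = pairs$read_id, stringsAsFactors = FALSE), out)
  out
}
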