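#' Build the stepwise rarefaction schedule
#'
#' Depths in steps of 1,000 up to 10,000, then 10,000 up to 100,000, then
#' 100,000 up to `min(max_depth, 700000)`.
#'
#' @param max_depth largest depth to consider (>= 1000).
#' @param n_reps resampling repetitions per depth (5 by default).
#' @return list of class `RarefactionSchedule` with `depths` and `n_reps`.
#' @export
default_schedule <- function(max_depth, n_reps = 5L) {
  stop_if_not(max_depth >= 1000, "max_depth must be >= 1000")
  top <- min(max_depth, 700000)
  depths <- c(seq(1000, min(top, 10000), by = 1000),
              if (top > 10000) seq(20000, min(top, 100000), by = 10000),
              if (top > 100000) seq(200000, top, by = 100000))
  structure(list(depths = depths, n_reps = as.integer(n_reps)),
            class = "RarefactionSchedule")
}

#' Rarefaction of taxon discovery
#'
#' For each repetition, reads are drawn without replacement in a nested
#' fashion (one random permutation per repetition; depth d takes its first d
#' reads), and the number of distinct taxa observed at every rank is
#' recorded. Nesting makes taxon counts exactly non-decreasing in depth
#' within a repetition. Depths exceeding the number of reads are dropped
#' with a warning. Reads unassigned at a rank do not create taxa at that
#' rank; taxa are keyed by their full lineage path so identical labels under
#' different parents are not conflated.
#'
#' @param assignments data.frame of per-read assignments with the six rank
#'   columns (`domain`..`genus`; NA = unassigned at that rank).
#' @param schedule a `RarefactionSchedule`.
#' @param seed integer seed.
#' @return data.frame of class `RarefactionCurve`: `depth`, `rank`, `mean`,
#'   `sd` of the distinct-taxon count across repetitions.
#' @export
rarefy <- function(assignments, schedule, seed = 1) {
  stop_if_not(nrow(assignments) > 0, "empty assignments")
  total <- nrow(assignments)
  depths <- schedule$depths[schedule$depths <= total]
  if (length(depths) < length(schedule$depths))
    warning("dropping scheduled depths larger than the number of reads")
  stop_if_not(length(depths) > 0, "no scheduled depth is <= the number of reads")
  # full lineage path per read and rank, NA propagated
  paths <- matrix(NA_character_, total, 6L, dimnames = list(NULL, RANKS))
  acc <- assignments[[RANKS[1L]]]
  paths[, 1L] <- acc
  for (r in 2:6) {
    acc <- ifelse(is.na(assignments[[RANKS[r]]]), NA_character_,
                  paste(acc, assignments[[RANKS[r]]], sep = ";"))
    paths[, r] <- acc
  }
  res <- with_seed(seed, {
    lapply(seq_len(schedule$n_reps), function(rep) {
      perm <- sample.int(total)
      vapply(depths, function(d) {
        sel <- perm[seq_len(d)]
        vapply(seq_len(6L), function(r) {
          length(unique(paths[sel, r][!is.na(paths[sel, r])]))
        }, numeric(1L))
      }, numeric(6L))
    })
  })
  arr <- simplify2array(res)                  # 6 ranks x depths x reps
  if (length(depths) == 1L) arr <- array(arr, dim = c(6L, 1L, schedule$n_reps))
  out <- expand.grid(rank = RANKS, depth = depths, stringsAsFactors = FALSE)
  out$mean <- as.vector(apply(arr, c(1L, 2L), mean))
  out$sd <- as.vector(apply(arr, c(1L, 2L), sd))
  out <- out[, c("depth", "rank", "mean", "sd")]
  class(out) <- c("RarefactionCurve", "data.frame")
  out
}

#' Detection check at a fixed rarefaction depth
#'
#' Flags a taxon as detected when at least `min_reads` of its reads appear
#' in every one of `n_reps` independent draws of `depth` reads (without
#' replacement) -- the criterion behind the claim that taxa above 0.1
#' percent abundance are identified with 10 or more sequences at a depth of
#' 10,000 reads.
#'
#' @param assignments per-read assignment data.frame (six rank columns).
#' @param rank rank at which taxa are counted (default `"genus"`).
#' @param depth draw size (default 10000).
#' @param min_reads detection threshold per draw (default 10).
#' @param n_reps number of draws (default 5).
#' @param seed integer seed.
#' @return data.frame with `taxon`, `fraction` (abundance among
#'   rank-assigned reads in the full sample), `min_reads_seen` (minimum
#'   count across draws) and `detected`.
#' @export
detection_check <- function(assignments, rank = "genus", depth = 10000L,
                            min_reads = 10L, n_reps = 5L, seed = 1) {
  total <- nrow(assignments)
  stop_if_not(depth <= total, "depth exceeds the number of reads")
  lab <- assignments[[rank]]
  taxa <- sort(unique(lab[!is.na(lab)]))
  counts <- with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      sel <- sample.int(total, depth)
      tab <- table(factor(lab[sel], levels = taxa))
      as.integer(tab)
    }, integer(length(taxa)))
  })
  if (length(taxa) == 1L) counts <- matrix(counts, nrow = 1L)
  mins <- apply(counts, 1L, min)
  full <- table(factor(lab, levels = taxa))
  data.frame(taxon = taxa,
             fraction = as.integer(full) / sum(!is.na(lab)),
             min_reads_seen = mins,
             detected = mins >= min_reads,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a rarefaction curve as long-format TSV
#'
#' @param curve a `RarefactionCurve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rarefaction_curve <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
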