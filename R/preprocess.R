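#' Default quality-filter parameters
#'
#' Leading/trailing base trimming at Q20, a 4-base sliding window at mean
#' Q20, and a 100 nt minimum length -- the standard short-read filtering
#' recipe for 16S data.
#'
#' @return list of thresholds.
#' @export
default_filter_params <- function() {
  list(leading_q = 20L, trailing_q = 20L, window_len = 4L, window_q = 20L,
       min_len = 100L)
}

#' Default paired-end merge parameters
#'
#' Overlap-based merging; amplicon pairs tolerate a high mismatch ratio over
#' a bounded overlap (max 80), shotgun pairs require near-perfect overlaps
#' (max 100, mismatch ratio 0.01).
#'
#' @param strategy `"amplicon"` or `"shotgun"`.
#' @return list with `min_overlap`, `max_overlap`, `max_mismatch_ratio`.
#' @export
default_merge_params <- function(strategy = c("amplicon", "shotgun")) {
  strategy <- match.arg(strategy)
  if (strategy == "amplicon")
    list(min_overlap = 10L, max_overlap = 80L, max_mismatch_ratio = 0.25)
  else
    list(min_overlap = 10L, max_overlap = 100L, max_mismatch_ratio = 0.01)
}

#' Quality-filter a single read
#'
#' Applies, in order: (1) strip 5' bases with quality below `leading_q`;
#' (2) strip 3' bases below `trailing_q`; (3) scan 4-base windows 5' to 3'
#' and truncate the read at the first base of the first window whose mean
#' quality falls below `window_q`; (4) reject the read if the final length
#' is below `min_len`.
#'
#' @param sequence read sequence.
#' @param quality phred+33 quality string of the same length.
#' @param params see [default_filter_params()].
#' @return list with `kept` (logical), `sequence`, `quality` (empty when
#'   rejected) and `reason` (`"ok"` or `"too_short"`).
#' @export
quality_filter <- function(sequence, quality, params = default_filter_params()) {
  stop_if_not(nchar(sequence) == nchar(quality),
              "sequence and quality must have equal length")
  q <- utf8ToInt(quality) - 33L
  stop_if_not(all(q >= 0L & q <= 93L), "malformed quality string")
  n <- length(q)
  lo <- 1L; hi <- n
  while (lo <= hi && q[lo] < params$leading_q) lo <- lo + 1L
  while (hi >= lo && q[hi] < params$trailing_q) hi <- hi - 1L
  if (hi >= lo + params$window_len - 1L && params$window_len > 0L) {
    qq <- q[lo:hi]
    cs <- cumsum(c(0L, qq))
    nw <- length(qq) - params$window_len + 1L
    means <- (cs[(params$window_len + 1L):(params$window_len + nw)] - cs[1:nw]) /
      params$window_len
    bad <- which(means < params$window_q)
    if (length(bad) > 0L) hi <- lo + bad[1L] - 2L
  }
  len <- max(hi - lo + 1L, 0L)
  if (len < params$min_len) {
    list(kept = FALSE, sequence = "", quality = "", reason = "too_short")
  } else {
    list(kept = TRUE, sequence = substr(sequence, lo, hi),
         quality = substr(quality, lo, hi), reason = "ok")
  }
}

#' Quality-filter a batch of reads
#'
#' @param sequences,qualities character vectors of equal length.
#' @param params see [default_filter_params()].
#' @return data.frame with `sequence`, `quality`, `kept`, `reason`.
#' @export
quality_filter_reads <- function(sequences, qualities,
                                 params = default_filter_params()) {
  res <- mapply(quality_filter, sequences, qualities,
                MoreArgs = list(params = params), SIMPLIFY = FALSE,
                USE.NAMES = FALSE)
  data.frame(sequence = vapply(res, `[[`, character(1L), "sequence"),
             quality = vapply(res, `[[`, character(1L), "quality"),
             kept = vapply(res, `[[`, logical(1L), "kept"),
             reason = vapply(res, `[[`, character(1L), "reason"),
             stringsAsFactors = FALSE)
}

# base-4 encoding of all k-mers of a sequence; windows containing non-ACGT
# are dropped
kmer_ids <- function(s, k) {
  v <- seq_to_int(s)
  n <- length(v)
  if (n < k) return(integer(0))
  m <- vapply(seq_len(k), function(j) v[j:(n - k + j)], integer(n - k + 1L))
  ids <- as.integer(m %*% 4L^((k - 1L):0L))
  ids[!is.na(ids)]
}

local_align_batch <- function(patterns, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(patterns),
                                Biostrings::DNAString(subject),
                                type = "local", substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 2)
}

#' Select reads aligning to 16S references
#'
#' A read is kept when its best local alignment (match +1, mismatch -1, gap
#' -2) against any reference sequence, on either strand, reaches
#' `min_identity` over at least `min_aln_len` aligned (gap-free) columns.
#' Candidate references are pre-screened with a shared 12-mer index; a read
#' sharing no 12-mer with any reference cannot reach 80 percent identity
#' over 50 columns and is discarded without alignment.
#'
#' @param sequences character vector of read sequences.
#' @param refset a `ReferenceSet`.
#' @param min_identity minimum identity over aligned columns (gaps
#'   excluded).
#' @param min_aln_len minimum number of aligned columns.
#' @param seed_k k-mer size of the candidate screen.
#' @param max_candidates number of candidate references aligned per read.
#' @return data.frame with `kept`, `identity`, `aln_len`, `best_ref`,
#'   `strand`.
#' @export
select_rrna_reads <- function(sequences, refset, min_identity = 0.80,
                              min_aln_len = 50, seed_k = 12L,
                              max_candidates = 4L) {
  stop_if_not(length(refset$seqs) > 0, "empty reference set")
  nref <- length(refset$seqs)
  ref_kmers <- lapply(refset$seqs, kmer_ids, k = seed_k)
  kvec <- unlist(ref_kmers, use.names = FALSE)
  rvec <- rep.int(seq_len(nref), lengths(ref_kmers))
  o <- order(kvec); kvec <- kvec[o]; rvec <- rvec[o]

  n <- length(sequences)
  out <- data.frame(kept = rep(FALSE, n), identity = NA_real_,
                    aln_len = NA_integer_, best_ref = NA_character_,
                    strand = NA_character_)
  if (n == 0L) return(out)
  rc_all <- rev_comp(sequences)

  hit_refs <- function(s) {
    q <- unique(kmer_ids(s, seed_k))
    if (length(q) == 0L) return(integer(0))
    lo <- findInterval(q - 0.5, kvec) + 1L
    hi <- findInterval(q + 0.5, kvec)
    keep <- hi >= lo
    if (!any(keep)) return(integer(0))
    rvec[unlist(Map(seq.int, lo[keep], hi[keep]), use.names = FALSE)]
  }

  # (read, ref, strand) alignment tasks, grouped by reference for batch calls
  tasks <- vector("list", n)
  for (i in seq_len(n)) {
    for (str in c("+", "-")) {
      s <- if (str == "+") sequences[i] else rc_all[i]
      hits <- hit_refs(s)
      if (length(hits) == 0L) next
      tab <- sort(table(hits), decreasing = TRUE)
      cand <- as.integer(names(tab))[seq_len(min(length(tab), max_candidates))]
      tasks[[i]] <- rbind(tasks[[i]],
                          data.frame(read = i, ref = cand, strand = str))
    }
  }
  tasks <- do.call(rbind, tasks[!vapply(tasks, is.null, logical(1L))])
  if (is.null(tasks) || nrow(tasks) == 0L) return(out)

  for (r in unique(tasks$ref)) {
    sel <- tasks[tasks$ref == r, ]
    pat <- ifelse(sel$strand == "+", sequences[sel$read], rc_all[sel$read])
    aln <- local_align_batch(pat, refset$seqs[[r]])
    nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
    span <- nm + nmm
    ident <- ifelse(span > 0, nm / span, 0)
    ok <- span >= min_aln_len & ident >= min_identity
    for (j in which(ok)) {
      i <- sel$read[j]
      if (!out$kept[i] || ident[j] > out$identity[i]) {
        out$kept[i] <- TRUE
        out$identity[i] <- ident[j]
        out$aln_len[i] <- span[j]
        out$best_ref[i] <- refset$taxa$taxon_id[r]
        out$strand[i] <- sel$strand[j]
      }
    }
  }
  out
}

#' Merge a read pair by overlap
#'
#' Every candidate overlap length between `min_overlap` and `max_overlap`
#' (capped by the mate lengths) between the forward read's 3' end and the
#' reverse-complemented reverse read's 5' end is scored by its mismatch
#' ratio; the minimum-ratio overlap wins (ties go to the longer overlap).
#' The pair is left unmerged when the best ratio exceeds
#' `max_mismatch_ratio`. In the merged overlap the higher-quality base is
#' taken at conflicting positions and the maximum quality at agreements.
#'
#' @param fwd_seq,fwd_qual forward mate sequence and phred+33 qualities.
#' @param rev_seq,rev_qual reverse mate (as sequenced; it is
#'   reverse-complemented internally).
#' @param params see [default_merge_params()].
#' @return list with `merged` (logical), `sequence`, `quality`, `overlap`,
#'   `mismatch_ratio`.
#' @export
merge_pairs <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                        params = default_merge_params("amplicon")) {
  stop_if_not(nchar(fwd_seq) > 0 && nchar(rev_seq) > 0, "both mates must be non-empty")
  f <- strsplit(fwd_seq, NULL)[[1L]]
  fq <- utf8ToInt(fwd_qual) - 33L
  r <- strsplit(rev_comp(rev_seq), NULL)[[1L]]
  rq <- rev(utf8ToInt(rev_qual) - 33L)
  lf <- length(f); lr <- length(r)
  lmax <- min(params$max_overlap, lf, lr)
  best_l <- NA_integer_; best_ratio <- Inf
  cand <- if (lmax >= params$min_overlap) seq.int(params$min_overlap, lmax) else integer(0)
  for (L in cand) {
    mism <- sum(f[(lf - L + 1L):lf] != r[1:L])
    ratio <- mism / L
    if (ratio < best_ratio || (ratio == best_ratio && L > best_l)) {
      best_ratio <- ratio; best_l <- L
    }
  }
  if (!is.finite(best_ratio) || best_ratio > params$max_mismatch_ratio) {
    return(list(merged = FALSE, sequence = NA_character_,
                quality = NA_character_, overlap = NA_integer_,
                mismatch_ratio = if (is.finite(best_ratio)) best_ratio else NA_real_))
  }
  L <- best_l
  oi_f <- (lf - L + 1L):lf
  of <- f[oi_f]; oq_f <- fq[oi_f]
  or_ <- r[1:L]; oq_r <- rq[1:L]
  take_f <- oq_f >= oq_r
  cons <- ifelse(of == or_, of, ifelse(take_f, of, or_))
  cons_q <- ifelse(of == or_, pmax(oq_f, oq_r), ifelse(take_f, oq_f, oq_r))
  seq_out <- paste(c(f[seq_len(lf - L)], cons, r[(L + 1L):lr][seq_len(lr - L)]),
                   collapse = "")
  qual_out <- int_to_phred(list(c(fq[seq_len(lf - L)], cons_q,
                                  rq[(L + 1L):lr][seq_len(lr - L)])))[[1L]]
  list(merged = TRUE, sequence = seq_out, quality = qual_out, overlap = L,
       mismatch_ratio = best_ratio)
}

#' Merge a batch of simulated pairs
#'
#' @param pairs data.frame from a simulator (or with the same mate columns).
#' @param params see [default_merge_params()].
#' @return data.frame with `read_id`, `merged`, `sequence`, `quality`,
#'   `overlap`, `mismatch_ratio`.
#' @export
merge_pair_table <- function(pairs, params = default_merge_params("amplicon")) {
  res <- lapply(seq_len(nrow(pairs)), function(i)
    merge_pairs(pairs$fwd_seq[i], pairs$fwd_qual[i], pairs$rev_seq[i],
                pairs$rev_qual[i], params))
  data.frame(read_id = pairs$read_id,
             merged = vapply(res, `[[`, logical(1L), "merged"),
             sequence = vapply(res, `[[`, character(1L), "sequence"),
             quality = vapply(res, `[[`, character(1L), "quality"),
             overlap = vapply(res, `[[`, integer(1L), "overlap"),
             mismatch_ratio = vapply(res, `[[`, numeric(1L), "mismatch_ratio"),
             stringsAsFactors = FALSE)
}

#' Preprocessing summary counts
#'
#' @param n_input,n_kept,n_merged counts from a preprocessing run.
#' @return one-row data.frame.
#' @export
preprocess_summary <- function(n_input, n_kept, n_merged = NA_integer_) {
  data.frame(input = n_input, kept = n_kept, merged = n_merged)
}
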