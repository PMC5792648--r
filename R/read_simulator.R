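#' Default sequencing error model
#'
#' Constant per-base substitution probability and flat base quality, with an
#' optional linear quality decay towards the 3' end (so that the sliding
#' window filter has something to act on when requested).
#'
#' @param sub_rate per-base substitution probability, in `[0, 0.1]`.
#' @param base_q Phred quality written for every base.
#' @param three_prime_decay total quality drop (Phred units) from the 5' to
#'   the 3' end of a read.
#' @return list with the three components.
#' @export
default_error_model <- function(sub_rate = 0.001, base_q = 35, three_prime_decay = 0) {
  stop_if_not(sub_rate >= 0 && sub_rate <= 0.1, "sub_rate must lie in [0, 0.1]")
  list(sub_rate = sub_rate, base_q = base_q, three_prime_decay = three_prime_decay)
}

quality_string <- function(len, model) {
  if (len == 0L) return("")
  q <- model$base_q - model$three_prime_decay * (seq_len(len) - 1L) / max(len - 1L, 1L)
  int_to_phred(list(as.integer(round(q))))[[1L]]
}

# apply i.i.d. substitution errors to a character vector of sequences
apply_errors <- function(seqs, sub_rate) {
  if (sub_rate <= 0 || length(seqs) == 0L) return(seqs)
  sp <- strsplit(seqs, NULL)
  lens <- lengths(sp)
  flat <- unlist(sp, use.names = FALSE)
  hit <- which(runif(length(flat)) < sub_rate)
  if (length(hit) > 0L) {
    cur <- match(flat[hit], BASES) - 1L
    flat[hit] <- BASES[((cur + sample(1:3, length(hit), replace = TRUE)) %% 4L) + 1L]
  }
  grp <- rep.int(seq_along(lens), lens)
  vapply(split(flat, grp), paste, character(1L), collapse = "")
}

make_pairs <- function(read_id, strategy, taxon_id, template_seqs, frag_start,
                       frag_end, read_len, model) {
  # forward mate covers the fragment 5' end on the plus strand, reverse mate
  # the fragment 3' end, reverse-complemented
  f_start <- frag_start
  f_end <- pmin(frag_start + read_len, frag_end)
  r_end <- frag_end
  r_start <- pmax(frag_end - read_len, frag_start)
  fwd <- substring(template_seqs, f_start + 1L, f_end)
  rev <- rev_comp(substring(template_seqs, r_start + 1L, r_end))
  fwd <- apply_errors(fwd, model$sub_rate)
  rev <- apply_errors(rev, model$sub_rate)
  qual_by_len <- vapply(sort(unique(c(nchar(fwd), nchar(rev)))),
                        quality_string, character(1L), model = model)
  names(qual_by_len) <- sort(unique(c(nchar(fwd), nchar(rev))))
  data.frame(read_id = read_id, strategy = strategy, taxon_id = taxon_id,
             fwd_seq = fwd, fwd_qual = unname(qual_by_len[as.character(nchar(fwd))]),
             rev_seq = rev, rev_qual = unname(qual_by_len[as.character(nchar(rev))]),
             fwd_start = f_start, fwd_end = f_end,
             rev_start = r_start, rev_end = r_end,
             stringsAsFactors = FALSE)
}

#' Simulate V4 amplicon read pairs
#'
#' Templates are sampled with weight proportional to cell fraction times 16S
#' copy number times amplifiability (the binary outcome of the in-silico PCR
#' check); every pair spans the amplicon product, the forward mate from its
#' 5' end and the reverse mate, reverse-complemented, from its 3' end.
#'
#' @param refset a `ReferenceSet`.
#' @param profile a `CommunityProfile` over the reference taxa.
#' @param n_pairs number of read pairs to emit.
#' @param read_len read length (paired-end 2 x 150 by default).
#' @param error_model see [default_error_model()].
#' @param seed integer seed.
#' @param pcr_params in-silico PCR matching parameters.
#' @return data.frame with one row per pair: mate sequences and qualities,
#'   ground-truth taxon and template intervals (0-based half-open; forward
#'   mate on `+`, reverse mate on `-`).
#' @export
simulate_amplicon <- function(refset, profile, n_pairs, read_len = 150,
                              error_model = default_error_model(), seed = 1,
                              pcr_params = default_match_params()) {
  stop_if_not(n_pairs >= 0, "n_pairs must be >= 0")
  vp <- virtual_pcr_refset(refset, pcr_params)
  w <- as.numeric(profile[refset$taxa$taxon_id]) * refset$taxa$copy_number * vp$pass
  stop_if_not(sum(w) > 0, "no amplifiable taxon in the community")
  with_seed(seed, {
    if (n_pairs == 0L) return(empty_pairs())
    idx <- sample.int(nrow(refset$taxa), n_pairs, replace = TRUE, prob = w)
    make_pairs(sprintf("amp_%07d", seq_len(n_pairs)), "amplicon",
               refset$taxa$taxon_id[idx], unname(refset$seqs[idx]),
               vp$product_start[idx], vp$product_end[idx], read_len, error_model)
  })
}

empty_pairs <- function() {
  data.frame(read_id = character(0), strategy = character(0),
             taxon_id = character(0), fwd_seq = character(0),
             fwd_qual = character(0), rev_seq = character(0),
             rev_qual = character(0), fwd_start = numeric(0),
             fwd_end = numeric(0), rev_start = numeric(0), rev_end = numeric(0))
}

# i.i.d. uniform decoy pool emulating the non-rRNA bulk of a shotgun library
decoy_pool <- function(n_seqs = 10L, len = 5000L) {
  vapply(seq_len(n_seqs), function(i) random_dna(len), character(1L))
}

simulate_shotgun <- function(refset, profile, n_pairs, rrna_read_fraction,
                             taxon_weight, strategy, read_len, insert_law,
                             error_model, seed) {
  stop_if_not(n_pairs >= 0, "n_pairs must be >= 0")
  stop_if_not(rrna_read_fraction > 0 && rrna_read_fraction <= 1,
              "rrna_read_fraction must lie in (0, 1]")
  with_seed(seed, {
    if (n_pairs == 0L) return(empty_pairs())
    is_rrna <- runif(n_pairs) < rrna_read_fraction
    n_r <- sum(is_rrna); n_b <- n_pairs - n_r
    out <- vector("list", 2L)
    if (n_r > 0L) {
      idx <- sample.int(nrow(refset$taxa), n_r, replace = TRUE, prob = taxon_weight)
      tl <- nchar(refset$seqs)[idx]
      ins <- pmax(1L, round(rnorm(n_r, insert_law$mean, insert_law$sd)))
      start <- floor(runif(n_r) * tl)
      end <- pmin(start + ins, tl)
      out[[1L]] <- make_pairs(sprintf("%s_%07d", substr(strategy, 9, 11),
                                      which(is_rrna)), strategy,
                              refset$taxa$taxon_id[idx], unname(refset$seqs[idx]),
                              start, end, read_len, error_model)
    }
    if (n_b > 0L) {
      pool <- decoy_pool()
      pidx <- sample.int(length(pool), n_b, replace = TRUE)
      tl <- nchar(pool)[pidx]
      ins <- pmax(1L, round(rnorm(n_b, insert_law$mean, insert_law$sd)))
      start <- floor(runif(n_b) * tl)
      end <- pmin(start + ins, tl)
      bg <- make_pairs(sprintf("%s_%07d", substr(strategy, 9, 11),
                               which(!is_rrna)), strategy, "background",
                       pool[pidx], start, end, read_len, error_model)
      bg$fwd_start <- bg$fwd_end <- bg$rev_start <- bg$rev_end <- NA_real_
      out[[2L]] <- bg
    }
    pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
    pairs[order(pairs$read_id), , drop = FALSE]
  })
}

#' Simulate shotgun DNA (metagenomic) read pairs
#'
#' A small configurable fraction of pairs derives from 16S templates (taxon
#' weight proportional to cell fraction times copy number, fragment start
#' uniform along the gene); the rest are decoy background pairs from a
#' random sequence pool, emulating the non-rRNA bulk of a metagenome.
#'
#' @inheritParams simulate_amplicon
#' @param rrna_read_fraction probability that a pair derives from a 16S
#'   template (real metagenomes sit well below 1 percent).
#' @param insert_law list with `mean` and `sd` of the normal insert-length
#'   law (truncated to the template).
#' @return data.frame of pairs as in [simulate_amplicon()]; background pairs
#'   carry `taxon_id = "background"` and NA template coordinates.
#' @export
simulate_shotgun_dna <- function(refset, profile, n_pairs,
                                 rrna_read_fraction = 0.004, read_len = 150,
                                 insert_law = list(mean = 300, sd = 30),
                                 error_model = default_error_model(), seed = 1) {
  w <- as.numeric(profile[refset$taxa$taxon_id]) * refset$taxa$copy_number
  simulate_shotgun(refset, profile, n_pairs, rrna_read_fraction, w,
                   "shotgun_dna", read_len, insert_law, error_model, seed)
}

#' Simulate shotgun RNA (metatranscriptomic) read pairs
#'
#' 16S pairs are drawn with taxon weight proportional to cell fraction times
#' per-cell expression rate; the operon copy number deliberately does not
#' enter the weight, which is what distinguishes transcript-level from
#' gene-level abundance.
#'
#' @inheritParams simulate_shotgun_dna
#' @export
simulate_shotgun_rna <- function(refset, profile, n_pairs,
                                 rrna_read_fraction = 0.9, read_len = 150,
                                 insert_law = list(mean = 300, sd = 30),
                                 error_model = default_error_model(), seed = 1) {
  w <- as.numeric(profile[refset$taxa$taxon_id]) * refset$taxa$expression_rate
  simulate_shotgun(refset, profile, n_pairs, rrna_read_fraction, w,
                   "shotgun_rna", read_len, insert_law, error_model, seed)
}

#' Write simulated pairs as FASTQ plus a truth table
#'
#' Writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq` (phred+33) and
#' `<prefix>_truth.tsv` (read_id, taxon_id, start, end, strand, strategy;
#' one row per mate).
#'
#' @param pairs data.frame from a simulator.
#' @param prefix output path prefix.
#' @return the three file paths, invisibly.
#' @export
write_read_pairs <- function(pairs, prefix) {
  write_fastq <- function(ids, seqs, quals, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  }
  f1 <- paste0(prefix, "_R1.fastq"); f2 <- paste0(prefix, "_R2.fastq")
  ft <- paste0(prefix, "_truth.tsv")
  write_fastq(paste0(pairs$read_id, "/1"), pairs$fwd_seq, pairs$fwd_qual, f1)
  write_fastq(paste0(pairs$read_id, "/2"), pairs$rev_seq, pairs$rev_qual, f2)
  truth <- rbind(
    data.frame(read_id = paste0(pairs$read_id, "/1"), taxon_id = pairs$taxon_id,
               start = pairs$fwd_start, end = pairs$fwd_end, strand = "+",
               strategy = pairs$strategy),
    data.frame(read_id = paste0(pairs$read_id, "/2"), taxon_id = pairs$taxon_id,
               start = pairs$rev_start, end = pairs$rev_end, strand = "-",
               strategy = pairs$strategy))
  write.table(truth, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2, ft))
}

#' Read a FASTQ file into sequences and qualities
#'
#' @param path FASTQ file (phred+33).
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}
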