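# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ranks6 <- c("domain", "phylum", "class", "order", "family", "genus")

# a small reference set without primer bias, used across modules
tiny_refset <- function() {
  fixture("tiny_refset", {
    lin <- generate_taxonomy(c(1, 2, 2, 2, 2, 4), seed = 11)
    generate_reference_set(lin, seed = 12, biased_fraction = 0)
  })
}

# the default 50-genus community scenario (biased, special lineage g02)
default_scenario <- function() {
  fixture("default_scenario", build_scenario(default_run_config(1)))
}

# minimal refset-like training object from raw sequences and genus labels
make_training_set <- function(seqs, genera) {
  n <- length(seqs)
  taxa <- data.frame(taxon_id = sprintf("t%d", seq_len(n)),
                     domain = rep("d1", n), phylum = rep("p1", n),
                     class = rep("c1", n), order = rep("o1", n),
                     family = rep("f1", n), genus = genera,
                     stringsAsFactors = FALSE)
  names(seqs) <- taxa$taxon_id
  list(seqs = seqs, taxa = taxa)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

random_phred <- function(n, qmin = 2, qmax = 40) {
  intToUtf8(sample(qmin:qmax, n, TRUE) + 33L)
}

# ---- independent brute-force oracles -------------------------------------

# naive per-base reimplementation of the sliding-window quality filter
bf_quality_filter <- function(sequence, quality, params = default_filter_params()) {
  q <- utf8ToInt(quality) - 33L
  s <- strsplit(sequence, NULL)[[1L]]
  while (length(q) > 0 && q[1] < params$leading_q) {
    q <- q[-1]; s <- s[-1]
  }
  while (length(q) > 0 && q[length(q)] < params$trailing_q) {
    q <- q[-length(q)]; s <- s[-length(s)]
  }
  if (length(q) >= params$window_len) {
    for (i in seq_len(length(q) - params$window_len + 1L)) {
      if (mean(q[i:(i + params$window_len - 1L)]) < params$window_q) {
        q <- q[seq_len(i - 1L)]; s <- s[seq_len(i - 1L)]
        break
      }
    }
  }
  if (length(s) < params$min_len) list(kept = FALSE)
  else list(kept = TRUE, sequence = paste(s, collapse = ""),
            quality = intToUtf8(q + 33L))
}

# exhaustive-offset reimplementation of the overlap merge (decision +
# overlap length only)
bf_merge_pairs <- function(fwd_seq, rev_seq, params) {
  f <- strsplit(fwd_seq, NULL)[[1L]]
  r <- strsplit(rev_comp(rev_seq), NULL)[[1L]]
  best <- NULL
  for (L in seq_len(min(params$max_overlap, length(f), length(r)))) {
    if (L < params$min_overlap) next
    ratio <- sum(f[(length(f) - L + 1L):length(f)] != r[1:L]) / L
    if (is.null(best) || ratio < best$ratio ||
        (ratio == best$ratio && L > best$overlap)) {
      best <- list(ratio = ratio, overlap = L)
    }
  }
  if (is.null(best) || best$ratio > params$max_mismatch_ratio) {
    list(merged = FALSE)
  } else {
    list(merged = TRUE, overlap = best$overlap, ratio = best$ratio)
  }
}

# per-offset degenerate primer site scan using the public IUPAC matcher
bf_find_sites <- function(template, primer_seq, params, orientation) {
  site <- if (orientation == "forward") primer_seq else rev_comp(primer_seq)
  codes <- strsplit(site, NULL)[[1L]]
  tb <- strsplit(template, NULL)[[1L]]
  k <- length(codes)
  a <- params$three_prime_exact_len
  anchor <- if (orientation == "forward") (k - a + 1L):k else seq_len(a)
  hits <- data.frame(start = integer(0), mismatches = integer(0))
  for (off in seq_len(length(tb) - k + 1L)) {
    mm <- !iupac_match(tb[off:(off + k - 1L)], codes)
    if (sum(mm[anchor]) == 0L && sum(mm[-anchor]) <= params$max_mismatches) {
      hits <- rbind(hits, data.frame(start = off - 1L,
                                     mismatches = sum(mm[-anchor])))
    }
  }
  hits
}
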