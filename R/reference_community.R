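#' Generate a random taxonomy
#'
#' Builds a six-rank taxonomy (domain, phylum, class, order, family, genus)
#' as a proper tree: every node at a rank has exactly one parent at the rank
#' above, and every parent has at least one child.
#'
#' @param counts_per_rank integer vector of length 6: number of distinct
#'   labels at each rank, in the order domain, phylum, class, order, family,
#'   genus. Must be non-decreasing (a child rank cannot have fewer labels
#'   than its parent rank).
#' @param seed integer seed; the function is a pure function of
#'   `(counts_per_rank, seed)`.
#' @return a data.frame with one row per genus and columns
#'   `domain`..`genus` holding the lineage labels.
#' @export
generate_taxonomy <- function(counts_per_rank, seed) {
  stop_if_not(length(counts_per_rank) == 6L && all(counts_per_rank >= 1),
              "counts_per_rank must be 6 integers, all >= 1")
  stop_if_not(all(diff(counts_per_rank) >= 0),
              "counts_per_rank must be non-decreasing from domain to genus")
  counts <- as.integer(counts_per_rank)
  with_seed(seed, {
    # parent index of each node, per rank; first k_{r-1} children pinned to
    # distinct parents so every parent keeps at least one child
    parents <- vector("list", 6L)
    for (r in 2:6) {
      k <- counts[r]; kp <- counts[r - 1L]
      p <- integer(k)
      p[seq_len(kp)] <- seq_len(kp)
      if (k > kp) p[(kp + 1L):k] <- sample.int(kp, k - kp, replace = TRUE)
      parents[[r]] <- p
    }
    labels <- lapply(seq_along(RANKS), function(r)
      sprintf("%s%02d", substr(RANKS[r], 1L, 1L), seq_len(counts[r])))
    lin <- matrix("", nrow = counts[6L], ncol = 6L,
                  dimnames = list(NULL, RANKS))
    for (g in seq_len(counts[6L])) {
      idx <- g
      for (r in 6:1) {
        lin[g, r] <- labels[[r]][idx]
        if (r > 1L) idx <- parents[[r]][idx]
      }
    }
    as.data.frame(lin, stringsAsFactors = FALSE)
  })
}

#' Default V4 primer pair
#'
#' The widely used 515F/806R universal primer pair targeting the V4
#' hypervariable region, written 5' to 3' with IUPAC degeneracy codes.
#'
#' @return a list with elements `fwd` and `rev`, each a list with `name`
#'   and `seq`.
#' @export
default_primer_pair <- function() {
  list(fwd = list(name = "515F", seq = "GTGYCAGCMGCCGCGGTAA"),
       rev = list(name = "806R", seq = "GGACTACNVGGGTWTCTAAT"))
}

iupac_expand <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], NULL)[[1L]]
}

# concrete realization of a degenerate primer: one base drawn per position
realize_primer <- function(primer_seq) {
  codes <- strsplit(primer_seq, NULL)[[1L]]
  paste(vapply(codes, function(cd) {
    e <- iupac_expand(cd)
    if (length(e) == 1L) e else sample(e, 1L)
  }, character(1L)), collapse = "")
}

# draw the block architecture: 9 variable blocks (V1..V9) separated by 8
# conserved blocks; the two conserved blocks flanking V4 are long enough to
# host a primer site plus its offset from the region boundary
draw_blocks <- function(site_offset, fwd_len, rev_len) {
  need3 <- site_offset + fwd_len
  need4 <- site_offset + rev_len
  for (i in seq_len(10000L)) {
    v <- sample(60:100, 9L, replace = TRUE)
    k <- sample(80:150, 8L, replace = TRUE)
    k[3L] <- sample(max(100L, need3):150L, 1L)
    k[4L] <- sample(max(100L, need4):150L, 1L)
    total <- sum(v) + sum(k)
    if (total >= 1400L && total <= 1600L) {
      lens <- integer(17L)
      lens[seq(1L, 17L, 2L)] <- v
      lens[seq(2L, 16L, 2L)] <- k
      ends <- cumsum(lens)
      starts <- ends - lens
      return(data.frame(
        type = rep(c("variable", "conserved"), length.out = 17L),
        index = c(rbind(1:9, c(1:8, NA)))[1:17],
        start = starts, end = ends))
    }
  }
  stop("could not draw a block architecture within the length bounds")
}

region_map_from_blocks <- function(blocks) {
  vb <- blocks[blocks$type == "variable", ]
  span <- function(i, j) c(vb$start[i], vb$end[j])
  cls <- list(`V1-V2` = span(1, 2), V3 = span(3, 3), V4 = span(4, 4),
              `V5-V6` = span(5, 6), `V7-V8` = span(7, 8), V9 = span(9, 9))
  data.frame(class = names(cls),
             start = vapply(cls, `[`, numeric(1), 1L),
             end = vapply(cls, `[`, numeric(1), 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a synthetic 16S reference set
#'
#' Produces full-length (~1.5 kb) 16S-like sequences for a set of lineages by
#' mutating a common ancestral ("anchor") sequence along the taxonomy tree,
#' with a low substitution rate inside conserved blocks and a high rate inside
#' the nine hypervariable blocks, so that related taxa are more similar and
#' conserved blocks stay near-identical across the community. Exact V4 primer
#' sites are written into every taxon; a configurable fraction of taxa instead
#' receives two substitutions inside the 3'-terminal bases of one primer site,
#' which disqualifies the template from PCR amplification under the default
#' in-silico PCR rule.
#'
#' @param lineages data.frame from [generate_taxonomy()].
#' @param n_variable_regions number of hypervariable blocks; only the
#'   canonical 9 is supported.
#' @param conserved_sub_rate root-to-tip substitution rate in conserved
#'   blocks, in `[0, 0.5]` and below `variable_sub_rate`.
#' @param variable_sub_rate root-to-tip substitution rate in variable blocks.
#' @param biased_fraction fraction of taxa receiving engineered primer-site
#'   mismatches; exactly `round(biased_fraction * n_taxa)` taxa are flagged.
#' @param copy_number_law list with `min`, `max` (uniform integer bounds for
#'   the 16S operon copy number) and optional `low_copy_genus`, a genus label
#'   whose taxa are forced to a single copy.
#' @param expression_law list with `meanlog`, `sdlog` (log-normal per-cell
#'   rRNA expression weights) and optional `high_expression_genus` /
#'   `high_expression_fold` for a lineage with boosted transcription.
#' @param seed integer seed.
#' @param primers primer pair as [default_primer_pair()].
#' @param strains_per_genus number of reference sequences generated per genus
#'   (strains diverge by `strain_sub_rate` in variable blocks).
#' @param strain_sub_rate within-genus substitution rate.
#' @param site_offset distance (nt) between each primer site and the V4
#'   boundary it flanks; sets the amplicon product length.
#' @return an object of class `ReferenceSet`: list with `anchor`, `seqs`
#'   (named character vector), `taxa` (per-taxon table with lineage, copy
#'   number, expression rate and engineered mismatch counts), `blocks`,
#'   `region_map`, `sites` (forward/reverse primer site intervals, 0-based
#'   half-open) and `primers`.
#' @export
generate_reference_set <- function(lineages,
                                   n_variable_regions = 9,
                                   conserved_sub_rate = 0.02,
                                   variable_sub_rate = 0.30,
                                   biased_fraction = 0,
                                   copy_number_law = list(min = 1, max = 7),
                                   expression_law = list(meanlog = 0, sdlog = 1),
                                   seed = 1,
                                   primers = default_primer_pair(),
                                   strains_per_genus = 1,
                                   strain_sub_rate = 0.02,
                                   site_offset = 75) {
  stop_if_not(n_variable_regions == 9, "only the canonical 9 variable regions are supported")
  stop_if_not(conserved_sub_rate >= 0 && conserved_sub_rate <= 0.5 &&
                variable_sub_rate >= 0 && variable_sub_rate <= 0.5,
              "substitution rates must lie in [0, 0.5]")
  stop_if_not(conserved_sub_rate < variable_sub_rate,
              "conserved_sub_rate must be below variable_sub_rate")
  stop_if_not(biased_fraction >= 0 && biased_fraction <= 1,
              "biased_fraction must lie in [0, 1]")
  stop_if_not(nrow(lineages) >= 1, "need at least one lineage")

  fwd_seq <- primers$fwd$seq; rev_seq <- primers$rev$seq
  with_seed(seed, {
    blocks <- draw_blocks(site_offset, nchar(fwd_seq), nchar(rev_seq))
    L <- max(blocks$end)
    region_map <- region_map_from_blocks(blocks)
    v4 <- region_map[region_map$class == "V4", ]
    sites <- list(
      fwd = c(start = v4$start - site_offset - nchar(fwd_seq),
              end = v4$start - site_offset),
      rev = c(start = v4$end + site_offset,
              end = v4$end + site_offset + nchar(rev_seq)))

    anchor <- sample(0:3, L, replace = TRUE)
    # anchor carries one concrete realization of each primer site
    anchor_fwd <- seq_to_int(realize_primer(fwd_seq))
    anchor_rev <- seq_to_int(rev_comp(realize_primer(rev_seq)))
    anchor[(sites$fwd["start"] + 1L):sites$fwd["end"]] <- anchor_fwd
    anchor[(sites$rev["start"] + 1L):sites$rev["end"]] <- anchor_rev

    cons_idx <- unlist(Map(function(s, e) (s + 1L):e,
                           blocks$start[blocks$type == "conserved"],
                           blocks$end[blocks$type == "conserved"]))
    var_idx <- unlist(Map(function(s, e) (s + 1L):e,
                          blocks$start[blocks$type == "variable"],
                          blocks$end[blocks$type == "variable"]))

    # walk the taxonomy tree: each of the six rank levels contributes 1/6 of
    # the root-to-tip substitution rate, so shared ancestry at higher ranks
    # translates into higher sequence similarity
    node_seq <- list(root = anchor)
    prefix_of <- function(row, r) paste(unlist(row[seq_len(r)]), collapse = ";")
    for (r in seq_along(RANKS)) {
      prefixes <- unique(vapply(seq_len(nrow(lineages)),
                                function(i) prefix_of(lineages[i, ], r), character(1)))
      for (p in prefixes) {
        parent <- if (r == 1L) "root" else sub(";[^;]+$", "", p)
        s <- node_seq[[parent]]
        s <- mutate_positions(s, cons_idx, conserved_sub_rate / 6)
        s <- mutate_positions(s, var_idx, variable_sub_rate / 6)
        node_seq[[p]] <- s
      }
    }

    n_gen <- nrow(lineages)
    taxa <- lineages[rep(seq_len(n_gen), each = strains_per_genus), , drop = FALSE]
    strain <- rep(seq_len(strains_per_genus), times = n_gen)
    taxa$taxon_id <- paste0(taxa$genus, "_", strain)
    rownames(taxa) <- NULL
    n_tax <- nrow(taxa)

    seqs <- vector("list", n_tax)
    for (i in seq_len(n_tax)) {
      s <- node_seq[[prefix_of(taxa[i, RANKS], 6L)]]
      if (strains_per_genus > 1L) {
        s <- mutate_positions(s, var_idx, strain_sub_rate)
        s <- mutate_positions(s, cons_idx, strain_sub_rate / 10)
      }
      seqs[[i]] <- s
    }

    # copy number and expression laws
    cn <- sample(copy_number_law$min:copy_number_law$max, n_tax, replace = TRUE)
    if (!is.null(copy_number_law$low_copy_genus))
      cn[taxa$genus %in% copy_number_law$low_copy_genus] <- 1L
    expr <- rlnorm(n_tax, expression_law$meanlog, expression_law$sdlog)
    if (!is.null(expression_law$high_expression_genus)) {
      fold <- if (is.null(expression_law$high_expression_fold)) 20 else
        expression_law$high_expression_fold
      expr[taxa$genus %in% expression_law$high_expression_genus] <-
        expr[taxa$genus %in% expression_law$high_expression_genus] * fold
    }

    # primer-biased taxa: drawn outside any designated special lineage so the
    # copy-number/expression effect and the primer effect stay separable
    special <- taxa$genus %in% c(copy_number_law$low_copy_genus,
                                 expression_law$high_expression_genus)
    n_biased <- round(biased_fraction * n_tax)
    eligible <- which(!special)
    stop_if_not(n_biased <= length(eligible),
                "biased_fraction too high for the number of non-special taxa")
    biased <- rep(FALSE, n_tax)
    if (n_biased > 0) biased[sample(eligible, n_biased)] <- TRUE

    fwd_codes <- strsplit(fwd_seq, NULL)[[1L]]
    rev_site_codes <- strsplit(rev_comp(rev_seq), NULL)[[1L]]
    fwd_mm <- integer(n_tax); rev_mm <- integer(n_tax)
    for (i in seq_len(n_tax)) {
      s <- seqs[[i]]
      site_fwd <- seq_to_int(realize_primer(fwd_seq))
      site_rev <- seq_to_int(rev_comp(realize_primer(rev_seq)))
      if (biased[i]) {
        if (runif(1) < 0.5) {
          site_fwd <- inject_anchor_mismatches(site_fwd, fwd_codes, end_3p = "right")
          fwd_mm[i] <- 2L
        } else {
          site_rev <- inject_anchor_mismatches(site_rev, rev_site_codes, end_3p = "left")
          rev_mm[i] <- 2L
        }
      }
      s[(sites$fwd["start"] + 1L):sites$fwd["end"]] <- site_fwd
      s[(sites$rev["start"] + 1L):sites$rev["end"]] <- site_rev
      seqs[[i]] <- s
    }

    seqs_chr <- vapply(seqs, int_to_seq, character(1L))
    names(seqs_chr) <- taxa$taxon_id
    taxa$copy_number <- as.integer(cn)
    taxa$expression_rate <- expr
    taxa$fwd_mismatches <- fwd_mm
    taxa$rev_mismatches <- rev_mm
    taxa$primer_biased <- biased
    taxa <- taxa[, c("taxon_id", RANKS, "copy_number", "expression_rate",
                     "fwd_mismatches", "rev_mismatches", "primer_biased")]

    structure(list(anchor = int_to_seq(anchor), seqs = seqs_chr, taxa = taxa,
                   blocks = blocks, region_map = region_map, sites = sites,
                   primers = primers),
              class = "ReferenceSet")
  })
}

# place 2 substitutions inside the 9 bases at the primer's 3' end; on the
# plus strand the 3' end of the forward site is its right edge, that of the
# reverse-complemented reverse site its left edge. Degenerate positions with
# a full {A,C,G,T} expansion cannot carry a mismatch and are skipped.
inject_anchor_mismatches <- function(site, codes, end_3p, n_mm = 2L, anchor_len = 9L) {
  n <- length(site)
  anchor_pos <- if (end_3p == "right") (n - anchor_len + 1L):n else seq_len(anchor_len)
  ok <- anchor_pos[vapply(codes[anchor_pos],
                          function(cd) length(iupac_expand(cd)) < 4L, logical(1L))]
  stop_if_not(length(ok) >= n_mm, "primer 3' anchor too degenerate to engineer mismatches")
  for (p in sample(ok, n_mm)) {
    allowed <- setdiff(BASES, iupac_expand(codes[p]))
    site[p] <- match(sample(allowed, 1L), BASES) - 1L
  }
  site
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat(sprintf("ReferenceSet: %d taxa, anchor length %d nt, %d biased taxa\n",
              nrow(x$taxa), nchar(x$anchor), sum(x$taxa$primer_biased)))
  invisible(x)
}

#' Draw a community profile
#'
#' Cell fractions for every taxon in the reference set, drawn from a
#' log-normal abundance law and normalised to sum to one. `lognormal_sigma
#' = 0` yields the uniform profile.
#'
#' @param refset a `ReferenceSet`.
#' @param lognormal_mu,lognormal_sigma parameters of the log-normal law.
#' @param seed integer seed.
#' @return named numeric vector of fractions (class `CommunityProfile`).
#' @export
generate_profile <- function(refset, lognormal_mu = 0, lognormal_sigma = 1.5, seed = 1) {
  stop_if_not(lognormal_sigma >= 0, "lognormal_sigma must be >= 0")
  stop_if_not(nrow(refset$taxa) >= 1, "empty reference set")
  with_seed(seed, {
    x <- rlnorm(nrow(refset$taxa), lognormal_mu, lognormal_sigma)
    p <- x / sum(x)
    names(p) <- refset$taxa$taxon_id
    structure(p, class = "CommunityProfile")
  })
}

#' Apply multiplicative abundance shifts to a profile
#'
#' Multiplies selected taxa by a fold factor and renormalises; used to derive
#' the second experimental condition (e.g. after a feedstock amendment) from
#' the first.
#'
#' @param profile a `CommunityProfile`.
#' @param effect_map named numeric vector: taxon_id -> multiplicative fold
#'   (> 0).
#' @param renormalize logical; renormalise to sum 1 (default).
#' @return perturbed `CommunityProfile`.
#' @export
perturb_profile <- function(profile, effect_map, renormalize = TRUE) {
  stop_if_not(all(effect_map > 0), "folds must be > 0")
  unknown <- setdiff(names(effect_map), names(profile))
  stop_if_not(length(unknown) == 0,
              paste("unknown taxa in effect_map:", paste(unknown, collapse = ", ")))
  p <- unclass(profile)
  p[names(effect_map)] <- p[names(effect_map)] * effect_map
  if (renormalize) p <- p / sum(p)
  structure(p, class = "CommunityProfile")
}

#' Write a reference set to plain-text files
#'
#' Writes `references.fasta` (one record per taxon), `lineage.tsv`
#' (taxon_id, semicolon-joined six-rank lineage), `attributes.tsv`
#' (copy number, expression rate, engineered mismatch counts) and
#' `region_map.yml` (anchor sequence, block table, region intervals and
#' primer site coordinates).
#'
#' @param refset a `ReferenceSet`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(refset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refset$seqs),
                              file.path(dir, "references.fasta"))
  lin <- data.frame(taxon_id = refset$taxa$taxon_id,
                    lineage = apply(refset$taxa[, RANKS], 1L, paste, collapse = ";"))
  write.table(lin, file.path(dir, "lineage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  attrs <- refset$taxa[, c("taxon_id", "copy_number", "expression_rate",
                           "fwd_mismatches", "rev_mismatches")]
  write.table(attrs, file.path(dir, "attributes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    anchor = refset$anchor,
    blocks = as.list(refset$blocks),
    region_map = as.list(refset$region_map),
    sites = lapply(refset$sites, as.list),
    primers = refset$primers), file.path(dir, "region_map.yml"))
  invisible(dir)
}

#' Read a reference set written by [write_reference_set()]
#'
#' @param dir directory containing the four files.
#' @return a `ReferenceSet`.
#' @export
read_reference_set <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "references.fasta"))
  lin <- read.table(file.path(dir, "lineage.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  ranks <- do.call(rbind, strsplit(lin$lineage, ";", fixed = TRUE))
  colnames(ranks) <- RANKS
  attrs <- read.table(file.path(dir, "attributes.tsv"), sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "region_map.yml"))
  taxa <- cbind(data.frame(taxon_id = lin$taxon_id, stringsAsFactors = FALSE),
                as.data.frame(ranks, stringsAsFactors = FALSE))
  taxa <- merge(taxa, attrs, by = "taxon_id", sort = FALSE)
  taxa$primer_biased <- taxa$fwd_mismatches > 0 | taxa$rev_mismatches > 0
  s <- as.character(seqs)
  structure(list(anchor = meta$anchor, seqs = s[taxa$taxon_id], taxa = taxa,
                 blocks = as.data.frame(meta$blocks),
                 region_map = as.data.frame(meta$region_map),
                 sites = lapply(meta$sites, unlist),
                 primers = meta$primers),
            class = "ReferenceSet")
}

#' Write / read a community profile as two-column TSV
#' @param profile a `CommunityProfile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  write.table(data.frame(taxon_id = names(profile), fraction = as.numeric(profile)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  structure(setNames(d$fraction, d$taxon_id), class = "CommunityProfile")
}
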