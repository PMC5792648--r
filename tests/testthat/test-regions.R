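test_that("locate_on_anchor recovers anchor coordinates of error-free reads", {
  rs <- tiny_refset()
  read <- substr(rs$anchor, 601, 750)
  loc <- locate_on_anchor(read, rs)
  expect_equal(loc$start, 600)
  expect_equal(loc$end, 750)
  expect_equal(loc$strand, "+")
  # reverse-complemented read maps to the same span on the minus strand
  loc2 <- locate_on_anchor(rev_comp(read), rs)
  expect_equal(loc2$start, 600)
  expect_equal(loc2$strand, "-")
  # background reads stay unplaced
  set.seed(5)
  locbg <- locate_on_anchor(random_seq(150), rs)
  expect_true(is.na(locbg$start))
})

test_that("taxon reads locate within a few bases of their truth interval", {
  rs <- tiny_refset()
  prof <- generate_profile(rs, seed = 1)
  rna <- simulate_shotgun_rna(rs, prof, 40, rrna_read_fraction = 1,
                              error_model = default_error_model(0), seed = 2)
  rna <- rna[nchar(rna$fwd_seq) >= 100, ]
  loc <- locate_on_anchor(rna$fwd_seq, rs)
  ok <- !is.na(loc$start)
  expect_gt(mean(ok), 0.9)
  # local alignment can clip a few divergent terminal bases of a
  # hypervariable block; placements stay within a handful of bases
  dev <- pmax(abs(loc$start[ok] - rna$fwd_start[ok]),
              abs(loc$end[ok] - rna$fwd_end[ok]))
  expect_gte(mean(dev <= 10), 0.9)
  expect_true(all(dev <= 25))
  # truth mode passes intervals straight through
  lt <- locate_on_anchor(rna$fwd_seq, rs, truth_mode = TRUE,
                         truth = data.frame(start = rna$fwd_start,
                                            end = rna$fwd_end))
  expect_equal(lt$start, rna$fwd_start)
})

test_that("assign_region applies the half-open midpoint rule", {
  rm <- data.frame(class = c("V3", "V4"), start = c(100, 300), end = c(200, 400))
  expect_equal(assign_region(310, 330, rm), "V4")         # midpoint 320
  expect_equal(assign_region(210, 290, rm), "none")       # gap midpoint
  # midpoint exactly at an interval end is outside (half-open)
  expect_equal(assign_region(390, 410, rm), "none")       # midpoint 400
  expect_equal(assign_region(398, 400, rm), "V4")         # midpoint 399
  expect_equal(assign_region(NA, NA, rm), "none")
})

test_that("has_v4 requires full coverage of the V4 interval", {
  rs <- tiny_refset()
  v4 <- rs$region_map[rs$region_map$class == "V4", ]
  expect_true(has_v4(rs$seqs[[1]], rs))
  expect_false(has_v4(substr(rs$anchor, 1, 400), rs))
  # template covering V4 except its last base
  expect_false(has_v4(substr(rs$anchor, 1, v4$end - 1), rs))
  expect_true(has_v4(substr(rs$anchor, 1, v4$end), rs))
})

test_that("region binning partitions located reads and matches truth", {
  sc <- default_scenario()
  rs <- sc$refset
  rna <- simulate_shotgun_rna(rs, sc$profile_a, 3000, rrna_read_fraction = 1,
                              error_model = default_error_model(0), seed = 9)
  # error-free reads, truth coordinates: binning equals truth midpoint class
  cls <- assign_region(rna$fwd_start, rna$fwd_end, rs$region_map)
  mid <- floor((rna$fwd_start + rna$fwd_end) / 2)
  truth_cls <- vapply(mid, function(m) {
    hit <- rs$region_map$class[m >= rs$region_map$start & m < rs$region_map$end]
    if (length(hit) == 1) hit else "none"
  }, character(1))
  expect_identical(cls, truth_cls)
  # partition: every read in exactly one class, counts add up
  expect_equal(sum(table(cls)), nrow(rna))
  # shotgun reads visit all six classes
  expect_true(all(rs$region_map$class %in% cls))
})

test_that("per-region reports normalise within class and handle empties", {
  regions <- data.frame(read_id = c("r1", "r2", "r3"),
                        class = c("V4", "V4", "V4"))
  cl <- data.frame(read_id = c("r1", "r2", "r3"),
                   domain = "d1", phylum = "p1", class = "c1", order = "o1",
                   family = "f1", genus = c("g1", "g1", "g2"),
                   stringsAsFactors = FALSE)
  rep1 <- per_region_report(regions, cl)
  expect_equal(rep1$summary$n_reads, 3L)
  expect_equal(rep1$summary$frac_genus, 1)
  expect_equal(sort(rep1$taxa$count), c(1L, 2L))
  # empty class -> zero row, no error
  regions2 <- rbind(regions, data.frame(read_id = "r4", class = "none"))
  cl2 <- rbind(cl, data.frame(read_id = "r4", domain = NA, phylum = NA,
                              class = NA, order = NA, family = NA, genus = NA))
  rep2 <- per_region_report(regions2, cl2)
  none_row <- rep2$summary[rep2$summary$class == "none", ]
  expect_equal(none_row$frac_genus, 0)
})

test_that("conserved-sequence content degrades genus-level assignment", {
  # conserved blocks are near-identical across taxa, so their words carry
  # no genus signal: reads dominated by conserved sequence are assigned at
  # genus far less often than reads rich in hypervariable bases (150 nt
  # reads always straddle some variable sequence, so the drop shows in the
  # variable-base content, not in the midpoint bin)
  sc <- default_scenario()
  rs <- sc$refset
  rna <- simulate_shotgun_rna(rs, sc$profile_a, 2500, rrna_read_fraction = 1,
                              error_model = default_error_model(0), seed = 31)
  rna <- rna[nchar(rna$fwd_seq) >= 100, ]
  model <- train_classifier(rs)
  cl <- classify_reads(rna$fwd_seq, model, n_bootstrap = 50, seed = 7,
                       read_ids = rna$read_id)
  vb <- rs$blocks[rs$blocks$type == "variable", ]
  varfrac <- vapply(seq_len(nrow(rna)), function(i) {
    s <- rna$fwd_start[i]; e <- rna$fwd_end[i]
    sum(pmax(0, pmin(e, vb$end) - pmax(s, vb$start))) / (e - s)
  }, numeric(1))
  assigned <- !is.na(cl$genus)
  conserved_heavy <- varfrac < 0.2
  variable_rich <- varfrac > 0.5
  expect_gt(sum(conserved_heavy), 20)
  expect_gt(mean(assigned[variable_rich]),
            mean(assigned[conserved_heavy]) + 0.1)
  # genus support rises with variable-base content
  expect_gt(cor(varfrac, cl$genus_support), 0.2)
})
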