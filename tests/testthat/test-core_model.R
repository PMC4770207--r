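test_that("target construction normalizes the alphabet and rejects junk", {
  t <- target_transcript("acgtACGT")
  expect_equal(t$sequence, "ACGUACGU")
  expect_equal(t$source_alphabet, "DNA")
  expect_equal(target_transcript("ACGU")$source_alphabet, "RNA")
  expect_error(target_transcript(""), "non-empty")
  expect_error(target_transcript("ACGN"), "outside")
  expect_error(target_transcript("AC-GU"), "outside")
})

test_that("design parameter validation enforces NUH and arm ranges", {
  expect_error(design_params(cut_triplets = "GUG"), "NUH")
  expect_error(design_params(cut_triplets = "GAC"), "NUH")
  expect_error(design_params(arm_min = 0), "arm_min")
  expect_error(design_params(arm_min = 5, arm_max = 3), "arm_min")
  expect_equal(design_params(cut_triplets = "gtc")$cut_triplets, "GUC")
  expect_error(design_env(context = "in_vivo"), "transcriptome")
})

test_that("find_cut_sites returns all occurrences, overlaps included", {
  expect_equal(nrow(find_cut_sites(target_transcript("AAAA"), "GUC")), 0L)

  s <- find_cut_sites(target_transcript("GUCGUC"), "GUC")
  expect_equal(s$index, c(0L, 3L))
  expect_equal(s$cut_pos, c(3L, 6L))
  expect_equal(s$site_id, c(0L, 1L))

  # overlapping occurrences of a self-overlapping triplet
  s2 <- find_cut_sites(target_transcript("AUUUUA"), "UUU")
  expect_equal(s2$index, c(1L, 2L))
})

test_that("find_cut_sites agrees with a naive scan oracle on fuzzed input", {
  set.seed(101)
  for (rep in 1:25) {
    seq <- random_rna(sample(10:200, 1))
    trip <- sample(c("GUC", "AUC", "CUC", "UUA", "GUA"), sample(1:3, 1))
    got <- find_cut_sites(target_transcript(seq), trip)
    expect_equal(got$index, o_scan_sites(seq, trip))
  }
})

test_that("candidate enumeration count matches the squared-range formula", {
  tgt <- make_transcript(200, data.frame(triplet = "GUC",
                                         position = c(50, 120)),
                         seed = 3, margin = 10)
  sites <- find_cut_sites(tgt, "GUC")

  p <- design_params(arm_min = 3, arm_max = 4)
  expect_equal(nrow(enumerate_candidates(tgt, sites, p)), 8L)  # 2 * 2^2

  p1 <- design_params(arm_min = 5, arm_max = 5)
  one <- enumerate_candidates(tgt, sites[1, ], p1)
  expect_equal(nrow(one), 1L)

  # fuzzed interior-site counts
  set.seed(77)
  for (rep in 1:10) {
    amin <- sample(1:4, 1); amax <- amin + sample(0:5, 1)
    nsite <- sample(1:4, 1)
    pos <- sort(sample(seq(20, 160, by = 5), nsite))
    tg <- make_transcript(200, data.frame(triplet = "GUC", position = pos),
                          seed = rep, margin = 15)
    st <- find_cut_sites(tg, "GUC")
    cc <- enumerate_candidates(tg, st,
                               design_params(arm_min = amin, arm_max = amax))
    expect_equal(nrow(cc), nsite * (amax - amin + 1)^2)
  }
})

test_that("sites near an end keep only the arm combinations that fit", {
  tgt <- target_transcript("GUCAAAAAAAAAA")   # site at index 0: no room 5'
  sites <- find_cut_sites(tgt, "GUC")
  p <- design_params(arm_min = 3, arm_max = 5)
  cands <- enumerate_candidates(tgt, sites, p)
  expect_equal(nrow(cands), 0L)   # arm 3 needs >= 3 nt 5' of the U

  tgt2 <- target_transcript("AAAGUCAAAAA")   # 3 nt 5' of U, 5 nt 3' of cut
  cands2 <- enumerate_candidates(tgt2, find_cut_sites(tgt2, "GUC"), p)
  # arm3 can only be 3 or 4 (segment ends at the N, index 3);
  # arm1 can be 3..5
  expect_equal(sort(unique(cands2$arm3_len)), c(3L, 4L))
  expect_equal(sort(unique(cands2$arm1_len)), c(3L, 4L, 5L))
  expect_equal(nrow(cands2), 6L)
})

test_that("arms pair perfectly with their target segments", {
  tgt <- make_transcript(80, data.frame(triplet = "GUC", position = 40),
                         seed = 9, margin = 12)
  sites <- find_cut_sites(tgt, "GUC")
  cands <- enumerate_candidates(tgt, sites, design_params(arm_min = 3,
                                                          arm_max = 8))
  for (r in seq_len(nrow(cands))) {
    cd <- cands[r, ]
    seg1 <- substr(tgt$sequence, cd$cut_pos + 1, cd$cut_pos + cd$arm1_len)
    seg3 <- substr(tgt$sequence, cd$index - cd$arm3_len + 2, cd$index + 1)
    expect_equal(cd$arm1_seq, o_revcomp(seg1))
    expect_equal(cd$arm3_seq, o_revcomp(seg3))
    # ribozyme = arm1 + core + arm3
    expect_equal(cd$ribozyme,
                 paste0(cd$arm1_seq, core_template()$core_seq, cd$arm3_seq))
  }
})

test_that("assembly reproduces the validated ribozyme set from its contexts", {
  yz <- yz_fixture_set()
  expect_equal(nrow(yz), 4L)
  for (r in seq_len(nrow(yz))) {
    tgt <- target_transcript(yz$target_context[r], yz$name[r])
    sites <- find_cut_sites(tgt, yz$triplet[r])
    s <- sites[sites$index == yz$site_index[r], ]
    expect_equal(nrow(s), 1L)
    rz <- assemble_ribozyme(tgt, s, yz$arm1_len[r], yz$arm3_len[r])
    expect_equal(rz, yz$ribozyme[r])
  }
})

test_that("assembly with empty arms yields the bare core and errors off-end", {
  tgt <- target_transcript("AAAGUCAAAAA")
  s <- find_cut_sites(tgt, "GUC")[1, ]
  expect_equal(assemble_ribozyme(tgt, s, 0, 0), core_template()$core_seq)
  expect_error(assemble_ribozyme(tgt, s, 10, 3), "past")
  expect_error(assemble_ribozyme(tgt, s, 3, 10), "past")
})

test_that("assembly is position-independent for identical site contexts", {
  ctx <- "GGCAGUCGCUAAG"
  tgt <- target_transcript(paste0("UUUU", ctx, "CCCCCCC", ctx, "UUUU"))
  sites <- find_cut_sites(tgt, "GUC")
  expect_equal(nrow(sites), 2L)
  r1 <- assemble_ribozyme(tgt, sites[1, ], 4, 4)
  r2 <- assemble_ribozyme(tgt, sites[2, ], 4, 4)
  expect_identical(r1, r2)
})

test_that("T7 templates carry the promoter and start the transcript on G", {
  t7 <- emit_t7_template("ACGU")
  expect_true(grepl("TAATACGACTCACTATAGCGACGT", t7["sense"], fixed = TRUE))
  expect_equal(unname(emit_t7_template("")["sense"]), "TAATACGACTCACTATAGCG")

  yz <- yz_fixture_set()
  for (r in seq_len(nrow(yz))) {
    t <- emit_t7_template(yz$ribozyme[r])
    expect_true(endsWith(t["antisense"], "CTATAGTGAGTCGTATTA"))
    expect_equal(unname(t["sense"]),
                 paste0("TAATACGACTCACTATAGCG", rna_to_dna(yz$ribozyme[r])))
  }
})

test_that("the core template keeps its conserved boxes in both models", {
  for (m in c("minimal", "extended")) {
    ct <- core_template(m)
    expect_true(grepl("CUGAUGA", ct$core_seq, fixed = TRUE))
    expect_true(grepl("GAAA", ct$core_seq, fixed = TRUE))
    # stem II pairs are Watson-Crick
    for (k in seq_len(nrow(ct$stem2_pairs))) {
      a <- substr(ct$core_seq, ct$stem2_pairs[k, 1], ct$stem2_pairs[k, 1])
      b <- substr(ct$core_seq, ct$stem2_pairs[k, 2], ct$stem2_pairs[k, 2])
      expect_true(o_can_pair(a, b))
    }
  }
  expect_equal(core_template("minimal")$core_seq,
               "CUGAUGAGUCGCUGAAAUGCGACGAAAC")
})
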