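# a small assembled candidate used throughout: GC-rich arms of 6/5 nt
.mk_cand <- function() {
  tgt <- target_transcript(paste0("AAAA", "GCGGCGGCGG", "GUC",
                                  "GCGGCGGCGG", "AAAA"))
  s <- find_cut_sites(tgt, "GUC")[1, ]
  core <- core_template()
  list(target = tgt, site = s, core = core,
       arm1_len = 6L, arm3_len = 5L,
       ribozyme = assemble_ribozyme(tgt, s, 6, 5, core))
}

test_that("core_intact recognizes the designed fold and its violations", {
  cd <- .mk_cand()
  db <- designed_fold(cd$arm1_len, cd$arm3_len, cd$core)
  expect_equal(nchar(db), nchar(cd$ribozyme))
  expect_true(core_intact(db, cd$arm1_len, cd$core))

  # fully unpaired: helix II not formed
  open <- strrep(".", nchar(cd$ribozyme))
  expect_false(core_intact(open, cd$arm1_len, cd$core))

  # a conserved CUGAUGA base pairing with an arm
  pt <- db_pairs(db)
  g_in_arm <- 2L                       # arm1 G
  c_core1 <- cd$arm1_len + 1L          # core C (CUGAUGA box)
  pt[g_in_arm] <- c_core1; pt[c_core1] <- g_in_arm
  expect_false(core_intact(pairs_db(pt), cd$arm1_len, cd$core))
})

test_that("open arms with the designed core give a structure score of zero", {
  cd <- .mk_cand()
  ens <- data.frame(dotbracket = designed_fold(cd$arm1_len, cd$arm3_len),
                    f_s = 1)
  q <- structure_quality(cd$ribozyme, ens, cd$arm1_len, cd$core)
  expect_equal(q$Q_s, 0)
  expect_equal(q$Q_f, 0)
  expect_true(q$core_intact)
})

test_that("a disrupted core costs exactly 50 on the Kelvin-sum scale", {
  cd <- .mk_cand()
  db0 <- designed_fold(cd$arm1_len, cd$arm3_len)
  # pair one conserved core base (an isolated pair: no stacking, so the
  # extraneous-stretch term is zero and the whole increment is the penalty)
  pt <- db_pairs(db0)
  pt[2L] <- cd$arm1_len + 1L; pt[cd$arm1_len + 1L] <- 2L
  db1 <- pairs_db(pt)

  for (w in c(1, 0.6)) {
    pad <- if (w < 1) data.frame(dotbracket = db0, f_s = 1 - w) else NULL
    e0 <- rbind(data.frame(dotbracket = db0, f_s = w), pad)
    e1 <- rbind(data.frame(dotbracket = db1, f_s = w), pad)
    q0 <- structure_quality(cd$ribozyme, e0, cd$arm1_len, cd$core)
    q1 <- structure_quality(cd$ribozyme, e1, cd$arm1_len, cd$core)
    expect_equal(q1$Q_f - q0$Q_f, 50 * w)
  }
})

test_that("Q_f is the weight-linear combination of per-structure scores", {
  cd <- .mk_cand()
  n <- nchar(cd$ribozyme)
  # two structures with real extraneous helices (arms folded onto each other)
  pt <- integer(n)
  for (k in 0:3) { pt[1 + k] <- n - k; pt[n - k] <- 1 + k }
  dbA <- pairs_db(pt)
  dbB <- designed_fold(cd$arm1_len, cd$arm3_len)
  qA <- structure_quality(cd$ribozyme,
                          data.frame(dotbracket = dbA, f_s = 1),
                          cd$arm1_len, cd$core)$Q_f
  qB <- structure_quality(cd$ribozyme,
                          data.frame(dotbracket = dbB, f_s = 1),
                          cd$arm1_len, cd$core)$Q_f
  expect_gt(qA, 0)
  mix <- data.frame(dotbracket = c(dbA, dbB), f_s = c(0.6, 0.4))
  qmix <- structure_quality(cd$ribozyme, mix, cd$arm1_len, cd$core)
  expect_equal(qmix$Q_f, 0.6 * qA + 0.4 * qB)
  expect_equal(qmix$Q_f, sum(mix$f_s * qmix$Q_s))

  # permutation invariance
  qperm <- structure_quality(cd$ribozyme, mix[2:1, ], cd$arm1_len, cd$core)
  expect_equal(qperm$Q_f, qmix$Q_f)
})

test_that("stretch decomposition merges across one 1x1 mismatch only", {
  n <- 40L
  pt <- integer(n)
  add <- function(pt, i, j) { pt[i] <- j; pt[j] <- i; pt }
  # helix A: (1,30) (2,29) (3,28); 1x1 gap; helix B: (5,26) (6,25)
  for (k in 0:2) pt <- add(pt, 1 + k, 30 - k)
  pt <- add(pt, 5, 26); pt <- add(pt, 6, 25)
  st <- ds_stretches(pt)
  expect_length(st, 1L)
  expect_equal(nrow(st[[1]]), 5L)

  # a second 1x1 gap starts a new stretch
  pt2 <- add(pt, 8, 23)
  st2 <- ds_stretches(pt2)
  expect_length(st2, 2L)

  # a 2x2 internal loop always splits
  pt3 <- integer(n)
  for (k in 0:2) pt3 <- add(pt3, 1 + k, 30 - k)
  pt3 <- add(pt3, 6, 25)
  expect_length(ds_stretches(pt3), 2L)
})

test_that("stretch decomposition matches the two-phase oracle on fuzz", {
  set.seed(41)
  for (rep in 1:60) {
    seq <- random_rna(sample(15:40, 1))
    pt <- o_random_structure(seq)
    got <- ds_stretches(pt)
    want <- o_stretches(pt)
    expect_equal(length(got), length(want))
    expect_equal(lapply(got, function(m) unname(m[, 1])),
                 lapply(want, function(m) unname(m[, 1])))
  }
})

test_that("removing a stretch never increases the structure score", {
  cd <- .mk_cand()
  n <- nchar(cd$ribozyme)
  set.seed(43)
  for (rep in 1:20) {
    pt <- o_random_structure(cd$ribozyme, tries = 40)
    q_full <- structure_quality(cd$ribozyme,
                                data.frame(dotbracket = pairs_db(pt), f_s = 1),
                                cd$arm1_len, cd$core)$Q_f
    st <- ds_stretches(pt, exclude_pairs = NULL)
    if (!length(st)) next
    drop <- st[[sample.int(length(st), 1)]]
    pt2 <- pt
    pt2[c(drop[, 1], drop[, 2])] <- 0L
    q_less <- structure_quality(cd$ribozyme,
                                data.frame(dotbracket = pairs_db(pt2), f_s = 1),
                                cd$arm1_len, cd$core)$Q_f
    expect_lte(q_less, q_full + 1e-9)
  }
})

test_that("designed stem II pairs are excluded from the stretch score", {
  cd <- .mk_cand()
  db <- designed_fold(cd$arm1_len, cd$arm3_len)
  pt <- db_pairs(db)
  # decomposing with the exclusion removes everything; without it the
  # stem II helix remains as one stretch
  ex <- cd$core$stem2_pairs + cd$arm1_len
  expect_length(ds_stretches(pt, exclude_pairs = ex), 0L)
  expect_length(ds_stretches(pt), 1L)
})
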