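test_that("ungapped identity maximises over all offsets", {
  expect_equal(ungapped_identity("AAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAA"), 1.0)
  expect_equal(ungapped_identity("AAAAAAAAAAAAAAA", "KKKKKKKKKKKKKKK"), 0.0)
  expect_equal(ungapped_identity("ACDEFGHIKLMNPQR", "ACDEFGHIKLMNPQW"), 14 / 15)
  # shifted repeat: best alignment is off-diagonal
  expect_equal(ungapped_identity("ACDEFGHIK", "CDEFGHIKL"), 8 / 9)
  expect_equal(ungapped_identity("ACDEF", "ACDEFGHIKLMNPQR"), 1.0)
  expect_error(ungapped_identity("", "ACD"), "non-empty")
})

test_that("shared 9-mer detection", {
  expect_true(shares_9mer("ACDEFGHIKLMNPQR", "GGEFGHIKLMNGGGG"))  # EFGHIKLMN
  expect_false(shares_9mer("ACDEFGHI", "ACDEFGHI"))               # length < 9
  expect_true(shares_9mer("ACDEFGHIK", "ACDEFGHIK"))
  expect_false(shares_9mer("ACDEFGHIK", "CDEFGHIKL"))
})

test_that("similarity = shared 9-mer OR identity strictly above 0.8", {
  # condition 1 fires although identity 9/15 = 0.6
  expect_true(is_similar("ACDEFGHIKLMNPQR", "GGEFGHIKLMNGGGG"))
  # 3 substitutions at positions 3, 8, 13 break every 9-mer window and leave
  # identity at exactly 12/15 = 0.8, which is NOT similar (threshold strict)
  p1 <- "ACDEFGHIKLMNPQR"
  p2 <- p1
  substr(p2, 3, 3) <- "W"; substr(p2, 8, 8) <- "W"; substr(p2, 13, 13) <- "W"
  expect_equal(ungapped_identity(p1, p2), 0.8)
  expect_false(shares_9mer(p1, p2))
  expect_false(is_similar(p1, p2))
  expect_false(is_similar("AAAAAAAAAAAAAAA", "KKKKKKKKKKKKKKK"))
})

test_that("similarity agrees with the brute-force oracle and is symmetric", {
  peps <- rand_peptides(60, len = 9:17, seed = 42)
  for (k in seq_len(150)) {
    i <- ((k - 1) %% 60) + 1
    j <- (k %% 60) + 1
    expect_equal(ungapped_identity(peps[i], peps[j]),
                 oracle_identity(peps[i], peps[j]))
    expect_identical(is_similar(peps[i], peps[j]),
                     oracle_similar(peps[i], peps[j]))
    expect_identical(is_similar(peps[i], peps[j]), is_similar(peps[j], peps[i]))
  }
  expect_true(all(is_similar(peps, peps)))  # reflexive (length >= 9)
})

test_that("similarity counts match full pairwise enumeration", {
  ch <- chain_abc()
  expect_identical(count_similar(unname(ch)), c(1L, 2L, 1L))
  expect_identical(count_similar(rep("ACDEFGHIKLMNPQR", 4)), rep(3L, 4))
  trio <- c("ACACACACACACACA", "DEDEDEDEDEDEDED", "KLKLKLKLKLKLKLK")
  expect_identical(count_similar(trio), c(0L, 0L, 0L))
  # against the oracle on a homolog-injected set
  w <- synthetic_world(seed = 5)
  d <- simulate_dataset(w, 80, mix = c(random = 0.5, tiles = 0.25,
                                       scan = 0.15, variants = 0.1))
  expect_identical(count_similar(d$sequence), oracle_count_similar(d$sequence))
})

test_that("forward Hobohm reduction is deterministic, independent, maximal", {
  ch <- chain_abc()
  red <- hobohm_reduce(unname(ch))
  expect_identical(red$kept, unname(ch[c("A", "C")]))
  expect_identical(red$discarded, unname(ch["B"]))

  peps <- c("ACACACACACACACA", "DEDEDEDEDEDEDED", "KLKLKLKLKLKLKLK")
  expect_identical(hobohm_reduce(peps)$kept, peps)     # fully dissimilar
  expect_equal(length(hobohm_reduce(rep("ACDEFGHIKLMNPQR", 5))$kept), 1L)

  w <- synthetic_world(seed = 9)
  d <- simulate_dataset(w, 120)
  r1 <- hobohm_reduce(d$sequence)
  r2 <- hobohm_reduce(d$sequence)
  expect_identical(r1, r2)                             # determinism
  # independence: no kept pair similar; maximality: discarded ~ some kept
  kept <- r1$kept
  pr <- similar_pairs(d$sequence)
  kept_set <- d$sequence %in% kept
  idx <- seq_along(d$sequence)
  for (k in seq_len(nrow(pr))) {
    expect_false(kept_set[pr$i[k]] && kept_set[pr$j[k]])
  }
  for (disc in r1$discarded) {
    expect_true(any(vapply(kept, function(kp) oracle_similar(disc, kp),
                           logical(1))))
  }
  expect_identical(tidy(r1)$n_similar, count_similar(d$sequence))
})

test_that("random removal is seed-dependent and keeps no similar pair", {
  ch <- unname(chain_abc())
  sizes <- vapply(1:40, function(s) length(random_reduce(ch, s)$kept),
                  integer(1))
  expect_true(all(sizes %in% c(1L, 2L)))
  expect_true(any(sizes == 1L) && any(sizes == 2L))  # instability is the point

  dis <- c("ACACACACACACACA", "DEDEDEDEDEDEDED", "KLKLKLKLKLKLKLK")
  for (s in 1:5) expect_identical(random_reduce(dis, s)$kept, dis)

  w <- synthetic_world(seed = 21)
  d <- simulate_dataset(w, 100)
  r <- random_reduce(d$sequence, seed = 3)
  kept_idx <- match(r$kept, d$sequence)
  pr <- similar_pairs(d$sequence)
  in_kept <- seq_along(d$sequence) %in% kept_idx
  expect_false(any(in_kept[pr$i] & in_kept[pr$j]))
})

test_that("Hobohm keeps at least as many peptides as random removal (mean over seeds)", {
  w <- synthetic_world(seed = 13)
  d <- simulate_dataset(w, 150, mix = c(random = 0.4, tiles = 0.3,
                                        scan = 0.2, variants = 0.1))
  hob <- length(hobohm_reduce(d$sequence)$kept)
  rnd <- vapply(1:20, function(s) length(random_reduce(d$sequence, s)$kept),
                integer(1))
  expect_lte(mean(rnd), hob)
})

test_that("SR construction reduces per partition and preserves order", {
  # the only similar pair straddles the binder boundary -> SR == ALL
  d <- affinity_table("X", c("ACDEFGHIKLMNPQR", "ACDEFGHIKLMNPQW",
                             "WYWYWYWYWYWYWYW"), c(100, 5000, 8000))
  ann <- similarity_reduce(d)
  expect_true(all(ann$in_sr))

  # a binder-side near-duplicate -> SR = ALL minus one
  d2 <- affinity_table("X", c("ACDEFGHIKLMNPQR", "ACDEFGHIKLMNPQW",
                              "WYWYWYWYWYWYWYW"), c(100, 200, 8000))
  ann2 <- similarity_reduce(d2)
  expect_equal(sum(ann2$in_sr), 2L)
  expect_identical(ann2$sequence, d2$sequence)  # order untouched

  # empty partition: all binders
  d3 <- affinity_table("X", c("ACDEFGHIKLMNPQR", "WYWYWYWYWYWYWYW"),
                       c(10, 20))
  expect_true(all(similarity_reduce(d3)$in_sr))
})

test_that("singular peptides have no similar partner in the ALL set", {
  ch <- chain_abc()
  d <- affinity_table("X", c(unname(ch), "KLKLKLKLKLKLKLK"),
                      c(10, 20, 30, 40))
  sp <- singular_peptides(d)
  expect_identical(sp$sequence, "KLKLKLKLKLKLKLK")

  dis <- affinity_table("X", c("ACACACACACACACA", "DEDEDEDEDEDEDED"),
                        c(10, 2000))
  expect_equal(nrow(singular_peptides(dis)), 2L)

  expect_message(
    dup <- affinity_table("X", rep("ACDEFGHIKLMNPQR", 3), c(10, 10, 10)))
  expect_equal(nrow(singular_peptides(dup)), 1L)  # duplicates already merged

  # hierarchy SP subset of SR subset of ALL on a homolog-rich dataset
  w <- synthetic_world(seed = 17)
  ds <- simulate_dataset(w, 150)
  ann <- similarity_reduce(ds)
  expect_true(all(ann$in_sr[ann$in_sp]))
  expect_lte(sum(ann$in_sr), nrow(ann))
})
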