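test_that("fragment partition tiles the block and assigns every marker once", {
  # published BTA5 bounds: 4.10 Mb spans five 1 Mb windows, last ~0.10 Mb
  map <- data.frame(chrom = "5",
                    pos = seq(70420628L, 74518588L, length.out = 99),
                    ref = "A", alt = "B")
  map$pos <- as.integer(round(map$pos))
  b <- define_haploblocks(map, data.frame(
    trait = "HP", chrom = "5", start_bp = 70420628L,
    end_bp = 74518588L))[[1L]]
  fc <- partition_fragments(b, map, width_bp = 1e6)
  expect_equal(nrow(fc$fragments), 5L)
  expect_equal(round((fc$fragments$end[5] - fc$fragments$start[5]) / 1e6, 2),
               0.10)
  # partition property: disjoint windows, every member in exactly one
  expect_equal(length(fc$marker_frag), length(b$markers))
  expect_true(all(fc$marker_frag %in% 1:5))
  for (f in 1:5) {
    inwin <- map$pos[b$markers] >= fc$fragments$start[f] &
      map$pos[b$markers] <= fc$fragments$end[f]
    expect_equal(which(fc$marker_frag == f), which(inwin))
  }

  # a window at least as wide as the block gives a single fragment
  fc1 <- partition_fragments(b, map, width_bp = 10e6)
  expect_equal(nrow(fc1$fragments), 1L)
})

test_that("Q columns require three occurrences and rows sum to ploidy", {
  map <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                    ref = "A", alt = "B")
  b <- define_haploblocks(map, data.frame(
    trait = "HP", chrom = "1", start_bp = 1L, end_bp = 1000L))[[1L]]
  fc <- partition_fragments(b, map, width_bp = 1e6)   # one fragment

  hapA <- c(1L, 0L, 1L, 0L); hapB <- c(0L, 1L, 0L, 1L)
  # five animals homozygous for one allele: a single column of 2s
  hom <- lapply(setNames(1:5, paste0("s", 1:5)),
                function(i) rbind(hapA, hapA))
  dA <- build_Q(fc, hom, min_occurrences = 3)
  expect_equal(ncol(dA$Q), 1L)
  expect_equal(unname(dA$Q[, 1L]), rep(2L, 5))

  # an allele on only two copies is dropped; its carrier is flagged
  mix <- c(lapply(setNames(1:4, paste0("s", 1:4)),
                  function(i) rbind(hapA, hapA)),
           list(s5 = rbind(hapB, hapB)))
  dB <- build_Q(fc, mix, min_occurrences = 3)
  expect_equal(ncol(dB$Q), 1L)
  expect_true(dB$partial[["s5"]])
  expect_false(any(dB$partial[paste0("s", 1:4)]))
  # fully resolved animals sum to 2, the flagged one to 0 here
  expect_equal(unname(rowSums(dB$Q)), c(2L, 2L, 2L, 2L, 0L))

  # nothing retained: fragment skipped with a warning
  rare <- list(s1 = rbind(hapA, hapB), s2 = rbind(hapA, hapB))
  expect_warning(d0 <- build_Q(fc, rare, min_occurrences = 3),
                 "fragment skipped")
  expect_equal(ncol(d0$Q), 0L)
})

test_that("variant regression is exact on haplotype-determined fixtures", {
  Q <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2),
             c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))

  # variant carried on every haplotype: y equals the row sums
  r1 <- regress_variant(rowSums(Q), Q)
  expect_equal(r1$d, rep(1, 3))
  expect_equal(r1$se, rep(0, 3))
  expect_equal(call_assignment(r1$d, r1$se), rep("present", 3))

  # variant on fragment-allele 2 only: exact unit vector
  y2 <- Q %*% c(0, 1, 0)
  r2 <- regress_variant(as.numeric(y2), Q)
  expect_equal(r2$d, c(0, 1, 0))
  expect_equal(call_assignment(r2$d, r2$se),
               c("absent", "present", "absent"))

  # one flipped dosage breaks haplotype determinism: inflated errors
  y3 <- as.numeric(y2); y3[1L] <- y3[1L] + 1
  r3 <- regress_variant(y3, Q)
  expect_true(any(r3$se >= 1e-4))
  expect_true("unreliable" %in% call_assignment(r3$d, r3$se))
})

test_that("regression matches the normal-equations oracle on random designs", {
  set.seed(14)
  for (rep in 1:10) {
    repeat {
      Q <- matrix(rbinom(8 * 3, 2, 0.4), 8, 3)
      if (qr(Q)$rank == 3L) break
    }
    y <- rnorm(8)
    fit <- regress_variant(y, Q)
    # brute-force normal equations
    QtQ_inv <- solve(crossprod(Q))
    d_star <- as.numeric(QtQ_inv %*% crossprod(Q, y))
    rss <- sum((y - Q %*% d_star)^2)
    se_star <- sqrt(rss / (8 - 3) * diag(QtQ_inv))
    expect_equal(fit$d, d_star, tolerance = 1e-10)
    expect_equal(fit$se, se_star, tolerance = 1e-10)
  }
})

test_that("degenerate regressions fail soft, never hard", {
  Q <- rbind(c(2, 0), c(0, 2))
  # fewer observations than columns
  under <- regress_variant(c(1), Q[1, , drop = FALSE])
  expect_true(all(is.na(under$d)))
  expect_true(all(under$flagged))
  # rank deficiency: a duplicated column taints itself and its twin, the
  # untouched column keeps its exact call
  Q3 <- rbind(c(2, 0), c(0, 2), c(1, 1))
  Qr <- cbind(Q3, Q3[, 2])
  y <- as.numeric(Q3 %*% c(1, 0))
  r <- regress_variant(y, Qr)
  expect_equal(which(r$flagged), c(2L, 3L))
  v <- call_assignment(r$d, r$se)
  expect_equal(v[1], "present")
  expect_equal(v[2:3], c("unreliable", "unreliable"))
})

test_that("verdict boundaries follow the exact-0/1 and strict-SE rules", {
  expect_equal(call_assignment(c(1, 0), c(0, 0)), c("present", "absent"))
  expect_equal(call_assignment(0.5, 0), "unreliable")
  expect_equal(call_assignment(1, 1e-4), "unreliable")      # strict <
  expect_equal(call_assignment(1, 0.99e-4), "present")
  expect_equal(call_assignment(1 + 2e-6, 0), "unreliable")  # outside tol
})

test_that("concordance logic on a hand-built fit: sets, hom rule, intersection", {
  # one fragment, three alleles A, B, C (columns 1..3); animals:
  # s1 = A/B (het), s2 = B/C (het), s3 = A/A (hom)
  hap_alleles <- array(NA_integer_, c(3, 2, 1),
                       dimnames = list(c("s1", "s2", "s3"), NULL, NULL))
  hap_alleles["s1", , 1] <- c(1L, 2L)
  hap_alleles["s2", , 1] <- c(2L, 3L)
  hap_alleles["s3", , 1] <- c(1L, 1L)
  verdicts <- rbind(
    v1 = c("present", "absent", "absent"),    # het in s1 and s2? s2: B,C -> absent,absent
    v2 = c("absent", "present", "absent"),    # het in s1 and s2
    v3 = c("absent", "present", "present"),   # het in s1, hom in s2
    v4 = c("present", "absent", "present"),   # het everywhere but breaks s3? no: s3 A/A equal
    v5 = c("unreliable", "present", "absent"))
  colnames(verdicts) <- c("f1.1", "f1.2", "f1.3")
  fm <- structure(list(
    design = list(Q = matrix(0L, 3, 3,
                             dimnames = list(c("s1", "s2", "s3"), NULL)),
                  hap_alleles = hap_alleles,
                  frag_cat = list(fragments = data.frame(frag = 1L),
                                  block = list(start_bp = 0L, name = "B"))),
    variants = data.frame(chrom = "1", pos = 11:15, ref = "A", alt = "C",
                          qual = 50, type = "SNP"),
    d = NULL, se = NULL, verdicts = verdicts, var_frag = rep(1L, 5),
    params = list(width_bp = 1e6)), class = "finemap_fit")

  status <- data.frame(sire = c("s1", "s2", "s3"),
                       status = c("het", "het", "hom"))
  cs <- concordant_variants(fm, status)
  # v1: s1 sees present/absent (in), s2 absent/absent (out)
  # v2, v4: in both; v3: s1 in, s2 present/present out; v5 is unreliable
  # on s1's allele A but cleanly heterozygous for s2
  expect_equal(cs$per_sire$s1, c(11L, 12L, 13L, 14L))
  expect_equal(cs$per_sire$s2, c(12L, 14L, 15L))
  expect_equal(cs$intersection, c(12L, 14L))

  # a variant whose verdicts differ across a homozygous sire's two copies
  # is impossible under the single-QTN assumption -> excluded globally
  hap_alleles["s3", , 1] <- c(1L, 2L)          # make s3's copies differ
  fm$design$hap_alleles <- hap_alleles
  cs2 <- concordant_variants(fm, status)
  expect_true(11L %in% cs2$excluded)           # present on A, absent on B
  expect_false(11L %in% cs2$per_sire$s1)

  # intersecting over more sires can only shrink the set
  expect_lte(length(cs$intersection), length(cs$per_sire$s1))
})

test_that("the planted QTN survives the whole pipeline on clean data", {
  st <- fixture_study()
  blocks <- fixture_blocks()
  bn <- names(blocks)[1L]
  haps <- sequenced_truth_haps(st, blocks[[bn]])
  fm <- finemap_block(blocks[[bn]], st$genotypes$map, st$sequence, haps)
  status <- truth_status(st)
  cs <- concordant_variants(fm, status)

  qtn_pos <- st$truth$qtn$pos[1L]
  cls <- attr(st$sequence, "variant_class")

  # haplotype-determined variants get exact verdicts, discordant never do
  callable <- apply(fm$verdicts, 1L,
                    function(v) any(v %in% c("present", "absent")))
  expect_true(all(callable[cls %in% c("qtn", "concordant")]))
  expect_false(any(callable[cls == "discordant"]))

  # the QTN is in every truth-heterozygous sire's set and the intersection
  het <- status$sire[status$status == "het"]
  for (s in intersect(het, names(cs$per_sire))) {
    expect_true(qtn_pos %in% cs$per_sire[[s]])
  }
  expect_true(qtn_pos %in% cs$intersection)

  # raising min_occurrences never widens Q
  fm10 <- suppressWarnings(
    finemap_block(blocks[[bn]], st$genotypes$map, st$sequence, haps,
                  min_occurrences = 10))
  expect_lte(ncol(fm10$design$Q), ncol(fm$design$Q))
})
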