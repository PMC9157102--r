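test_that("drive-free parents transmit Mendelian gametes", {
  p <- measured_params()
  d <- germline_gamete_distribution(genotype(c("WT", "WT")), p)
  expect_equal(sum(d$probability), 1)
  expect_equal(d$probability[d$drive_allele == "WT" &
                             d$offtarget_allele == "INTACT"], 1)
  # heterozygous at the off-target site, no drive: 50/50, uncut
  d2 <- germline_gamete_distribution(
    genotype(c("WT", "R2"), c("INTACT", "DISRUPTED")), p)
  agg <- tapply(d2$probability, d2$offtarget_allele, sum)
  expect_equal(as.numeric(agg[c("INTACT", "DISRUPTED")]), c(0.5, 0.5))
})

test_that("drive heterozygote gametes follow the competing-event model", {
  p <- drive_params(conversion_female = 0.767, conversion_male = 0.767,
                    germline_resistance_total = 0.222, relative_r1_rate = 0)
  d <- germline_gamete_distribution(genotype(c("DRIVE", "WT")), p)
  marg <- tapply(d$probability, d$drive_allele, sum)
  expect_equal(unname(marg["DRIVE"]), 0.5 + 0.5 * 0.767)
  expect_equal(unname(marg["R2"]), 0.5 * 0.222)
  expect_equal(unname(marg["WT"]), 0.5 * (1 - 0.767 - 0.222))
  expect_equal(unname(marg["R1"]), 0)
})

test_that("gamete distribution matches a Monte-Carlo event-sequence oracle", {
  # independent oracle: simulate the germline event sequence directly
  set.seed(42)
  p <- drive_params(conversion_female = 0.6, conversion_male = 0.6,
                    germline_resistance_total = 0.3,
                    relative_r1_rate = 0.2, offtarget_germline_cut_rate = 0.7)
  n <- 2e5
  alleles <- character(n)
  for (i in seq_len(n)) {
    pair <- c("DRIVE", "WT")
    if (pair[2] == "WT") {
      u <- runif(1)
      pair[2] <- if (u < 0.6) "DRIVE"
                 else if (u < 0.6 + 0.3 * 0.2) "R1"
                 else if (u < 0.6 + 0.3) "R2" else "WT"
    }
    alleles[i] <- sample(pair, 1)
  }
  mc <- table(factor(alleles, levels = c("WT", "DRIVE", "R1", "R2"))) / n
  d <- germline_gamete_distribution(genotype(c("DRIVE", "WT")), p)
  marg <- tapply(d$probability, d$drive_allele, sum)[c("WT", "DRIVE", "R1", "R2")]
  se <- sqrt(pmax(marg * (1 - marg), 1e-9) / n)
  expect_true(all(abs(unname(mc) - unname(marg)) < 3 * se + 1e-3))
})

test_that("without Cas9 the split drive transmits Mendelianly", {
  p <- drive_params(cas9_present = FALSE)
  d <- germline_gamete_distribution(genotype(c("DRIVE", "WT")), p)
  marg <- tapply(d$probability, d$drive_allele, sum)
  expect_equal(as.numeric(marg[c("DRIVE", "WT")]), c(0.5, 0.5))
})

test_that("off-target cut rate 1 disrupts every gamete of a drive carrier", {
  p <- drive_params(offtarget_germline_cut_rate = 1)
  d <- germline_gamete_distribution(
    genotype(c("DRIVE", "WT"), c("INTACT", "INTACT")), p)
  expect_equal(sum(d$probability[d$offtarget_allele == "DISRUPTED"]), 1)
})

test_that("gamete distributions are normalized across random parameters", {
  set.seed(11)
  for (rep in 1:20) {
    p <- random_params()
    dpair <- sample(c("WT", "DRIVE", "R1", "R2"), 2, replace = TRUE)
    opair <- sample(c("INTACT", "DISRUPTED"), 2, replace = TRUE)
    sex <- sample(c("FEMALE", "MALE"), 1)
    d <- germline_gamete_distribution(genotype(dpair, opair, sex), p)
    expect_equal(sum(d$probability), 1, tolerance = 1e-12)
    expect_true(all(d$probability >= 0))
  }
})

test_that("embryo cutting leaves drive-free mothers' offspring unchanged", {
  p <- measured_params()
  st <- founder_state(0.3, p)
  out <- apply_embryo_cutting(st, genotype(c("WT", "WT")), p)
  expect_equal(unclass(out), unclass(st))
})

test_that("embryo cutting removes WT alleles independently per allele", {
  p <- drive_params(embryo_cut_rate = 0.522, relative_r1_rate = 0)
  st <- founder_state(0, p)  # all WT/WT
  out <- apply_embryo_cutting(st, genotype(c("DRIVE", "WT")), p)
  df <- as.data.frame(out)
  wtwt <- sum(df$frequency[df$genotype_drive == "WT/WT" & df$sex == "FEMALE"])
  expect_equal(wtwt, (1 - 0.522)^2)  # enumerating cut/no-cut of both alleles
  # full cutting leaves no WT allele
  p1 <- drive_params(embryo_cut_rate = 1)
  out1 <- apply_embryo_cutting(st, genotype(c("DRIVE", "WT")), p1)
  df1 <- as.data.frame(out1)
  expect_equal(sum(df1$frequency[grepl("WT", df1$genotype_drive)]), 0)
})
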