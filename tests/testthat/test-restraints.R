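table1 <- fret_table1()

test_that("the packaged FRET table is complete and well formed", {
  expect_s3_class(table1, "fret_table")
  expect_identical(nrow(table1), 90L)
  expect_identical(sum(table1$state == "ca_saturated"), 45L)
  expect_identical(sum(table1$state == "ca_free"), 45L)
  expect_true(all(table1$rbar_A > 0 & table1$hw_A > 0))
})

test_that("restraint bounds follow the FRET-to-FRET+7 rule", {
  recs <- build_restraints(table1, state = "ca_saturated")
  sat <- table1[table1$state == "ca_saturated", ]
  expect_identical(nrow(recs), 45L)
  expect_identical(recs$low, sat$rbar_A)
  expect_identical(recs$up1, sat$rbar_A + 7)
  expect_identical(recs$up2, recs$up1 + 2)
  # the worked example pair
  row <- recs[recs$site_i == "cTnI:131" & recs$site_j == "cTnT:240", ]
  expect_equal(row$low, 48.1)
  expect_equal(row$up1, 55.1)

  # one record per input row, bijectively
  free <- build_restraints(table1, state = "ca_free")
  expect_identical(nrow(free), 45L)
  expect_identical(free$label,
                   paste0(free$site_i, "--", free$site_j, "/ca_free"))

  # alternative schemes
  sym <- build_restraints(table1, state = "ca_free", scheme = "sym7")
  expect_equal(sym$up1 - sym$low, rep(14, 45), tolerance = 1e-12)
  pt <- build_restraints(table1, state = "ca_free", scheme = "point")
  expect_identical(pt$low, pt$up1)

  # ordering invariant under every scheme
  for (r in list(recs, free, sym, pt))
    expect_true(all(r$low > 0 & r$low <= r$up1 & r$up1 <= r$up2))
})

test_that("half-width maps to a Boltzmann-consistent force constant", {
  # closed-form check by independent arithmetic
  kb <- 0.0083144621
  expect_equal(force_constant_from_hw(10.2, 300),
               kb * 300 / (10.2 / 2.35 / 10)^2)
  # inverse-square law and limits
  expect_equal(force_constant_from_hw(10) / force_constant_from_hw(20), 4)
  expect_lt(force_constant_from_hw(1e6), 1e-8)
  expect_error(force_constant_from_hw(0), "positive")
})

test_that("restraint writer and reader are inverse on the table records", {
  recs <- build_restraints(table1, state = "ca_saturated")
  f1 <- tempfile(fileext = ".itp")
  write_distance_restraints(recs, f1)
  lines <- readLines(f1)
  expect_identical(lines[1], "[ distance_restraints ]")
  # unit conversion: first record low = 48.1 A -> 4.8100 nm
  expect_match(lines[3], "4\\.8100")
  back <- read_distance_restraints(f1)
  expect_equal(back$low, recs$low, tolerance = 1e-9)
  expect_equal(back$up1, recs$up1, tolerance = 1e-9)
  expect_equal(back$up2, recs$up2, tolerance = 1e-9)
  expect_equal(back$kfac, recs$kfac, tolerance = 1e-6)
  expect_identical(back$site_i, recs$site_i)
  # write(read(write(x))) is byte-identical
  f2 <- tempfile(fileext = ".itp")
  write_distance_restraints(back, f2)
  expect_identical(readLines(f2), lines)
})

test_that("writer/reader round-trip holds on random record sets", {
  set.seed(99)
  for (k in 1:100) {
    n <- sample(1:8, 1)
    low <- round(runif(n, 10, 70), 2)
    recs <- data.frame(
      ai = sample(1000, n), aj = sample(1000, n),
      site_i = paste0("cTnI:", sample(200, n)),
      site_j = paste0("cTnT:", sample(300, n)),
      low = low, up1 = low + round(runif(n, 0, 10), 2),
      kfac = round(runif(n, 1, 900), 4), stringsAsFactors = FALSE)
    recs$up2 <- recs$up1 + 2
    recs$label <- paste0(recs$site_i, "--", recs$site_j, "/ca_free")
    class(recs) <- c("restraint_set", "data.frame")
    f <- tempfile()
    write_distance_restraints(recs, f)
    back <- read_distance_restraints(f)
    expect_equal(back$low, recs$low, tolerance = 1e-9)
    expect_equal(back$up1, recs$up1, tolerance = 1e-9)
    expect_equal(back$kfac, recs$kfac, tolerance = 1e-9)
    expect_identical(back$ai, recs$ai)
    expect_identical(back$label, recs$label)
    unlink(f)
  }
})

test_that("empty and duplicate record sets are handled", {
  empty <- build_restraints(table1, "ca_free")[0, ]
  f <- tempfile()
  write_distance_restraints(empty, f)
  expect_identical(nrow(read_distance_restraints(f)), 0L)
  dup <- build_restraints(table1, "ca_free")[c(1, 1), ]
  expect_warning(write_distance_restraints(dup, f), "duplicate")
  expect_identical(nrow(read_distance_restraints(f)), 2L)
})

test_that("restraint scoring measures flat-bottom violations", {
  # toy three-site structure with prescribed distances
  D <- matrix(c(0, 30, 50,
                30, 0, 40,
                50, 40, 0), 3, byrow = TRUE)
  st <- make_structure("two_domain_dumbbell", site_distances = D)
  anchors <- attr(st, "anchors")
  idx <- sapply(seq_len(3), function(i)
    which(st$atoms$chain == anchors$chain[i] &
            st$atoms$resno == anchors$resno[i] &
            st$atoms$elety == "CA"))
  recs <- data.frame(
    ai = idx[c(1, 1, 2)], aj = idx[c(2, 3, 3)],
    site_i = paste0("s:", c(1, 1, 2)), site_j = paste0("s:", c(2, 3, 3)),
    low = c(30, 55, 20), up1 = c(37, 60, 37), up2 = c(39, 62, 39),
    kfac = 10, label = "t", stringsAsFactors = FALSE)
  scored <- score_restraints(st, recs)
  expect_equal(scored$d_actual, c(30, 50, 40), tolerance = 1e-6)
  # d = low exactly -> no violation; below low -> deficit; above up1 -> excess
  expect_equal(scored$violation, c(0, 5, 3), tolerance = 1e-6)
  expect_equal(attr(scored, "fraction_satisfied"), 1 / 3)
})

test_that("restraints drawn inside their bounds score zero violation", {
  set.seed(5)
  for (k in 1:20) {
    d <- runif(1, 20, 60)
    st <- make_structure("two_domain_dumbbell", site_distances = d)
    anchors <- attr(st, "anchors")
    idx <- sapply(1:2, function(i)
      which(st$atoms$chain == anchors$chain[i] &
              st$atoms$resno == anchors$resno[i] &
              st$atoms$elety == "CA"))
    low <- d - runif(1, 0, 5)
    recs <- data.frame(ai = idx[1], aj = idx[2], site_i = "a", site_j = "b",
                       low = low, up1 = d + runif(1, 0, 5),
                       up2 = d + 7, kfac = 1, label = "x",
                       stringsAsFactors = FALSE)
    expect_identical(score_restraints(st, recs)$violation, 0)
  }
})

test_that("unresolvable sites raise a mapping error naming the offender", {
  st <- two_site_structure(30)
  map <- tnc_map()
  tab <- table1[1, ]             # cTnI:131 is not in the toy structure
  expect_error(build_restraints(tab, state = "ca_saturated",
                                site_map = map, structure = st),
               "cTnI")
  # mapped subunit, absent residue: the error carries the full site
  map2 <- site_map(copies = list(c(cTnI = "A", cTnT = "A")))
  expect_error(build_restraints(tab, state = "ca_saturated",
                                site_map = map2, structure = st),
               "cTnI:131")
})
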