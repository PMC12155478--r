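test_that("the packaged concentration table parses with censoring and round-trips", {
  tab <- fixture_peaks()
  expect_length(unique(tab$compound), 66)
  expect_length(unique(tab$sample), 8)
  expect_setequal(unique(tab$region), c("HY", "LM", "SX", "YT"))

  # censored cells carry no mean/sd
  nd <- tab[!tab$detected, ]
  expect_gt(nrow(nd), 0)
  expect_true(all(is.na(nd$mean_conc)) && all(is.na(nd$sd)))
  # the blank cells of the source table (caryophyllene) are censored
  cary <- tab[tab$compound == "Caryophyllene", ]
  expect_false(any(cary$detected[cary$sample %in% c("LM-P", "SX-S", "SX-P")]))

  # write . parse is the identity, byte for byte on canonical files
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_peak_table(tab, tmp)
  expect_identical(readLines(tmp),
                   readLines(aromarker_example("tongcheng_peak_table.csv")))
  expect_identical(read_peak_table(tmp), tab)
})

test_that("a minimal file with an n.d. cell parses as not detected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,HY-S_mean,HY-S_sd", "linalool,n.d.,n.d."), tmp)
  tab <- read_peak_table(tmp)
  expect_false(tab$detected)
  expect_true(is.na(tab$mean_conc))
})

test_that("malformed peak tables are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound,HY-S_mean,HY-S_sd", "a,1,0.1", "a,2,0.2"), tmp)
  expect_error(read_peak_table(tmp), "duplicate")
  writeLines(c("compound,HY-S_mean,HY-S_sd", "a,-1,0.1"), tmp)
  expect_error(read_peak_table(tmp), "negative")
  writeLines(c("compound,ZZ-S_mean,ZZ-S_sd", "a,1,0.1"), tmp)
  expect_error(read_peak_table(tmp), "unknown region/grade")
})

test_that("region presence follows the detected-in-at-least-one-batch rule", {
  means <- rbind(
    c1 = c(1, NA, NA, NA, 2, 2, NA, NA),
    c2 = c(NA, NA, NA, NA, NA, NA, NA, 5),
    c3 = c(1, 1, 1, 1, 1, 1, 1, 1)
  )
  colnames(means) <- c("HY-S", "HY-P", "LM-S", "LM-P",
                       "SX-S", "SX-P", "YT-S", "YT-P")
  tab <- make_peak_tbl(means)
  pres <- region_presence(tab)
  # brute-force enumeration of the hand-set censoring pattern
  expect_setequal(pres$region[pres$compound == "c1"], c("HY", "SX"))
  expect_setequal(pres$region[pres$compound == "c2"], "YT")
  expect_setequal(pres$region[pres$compound == "c3"],
                  c("HY", "LM", "SX", "YT"))

  # with nothing censored every compound is present in every region
  full <- make_peak_tbl(matrix(1, 2, 8, dimnames = list(c("c1", "c2"), colnames(means))))
  expect_equal(nrow(region_presence(full)), 2 * 4)
})

test_that("venn partition equals an exhaustive subset tally and is consistent", {
  set.seed(7)
  samples <- c("HY-S", "HY-P", "LM-S", "LM-P", "SX-S", "SX-P", "YT-S", "YT-P")
  means <- matrix(ifelse(runif(5 * 8) < 0.45, NA, 1), 5, 8,
                  dimnames = list(paste0("c", 1:5), samples))
  means[1, ] <- 1  # keep presence non-empty
  tab <- make_peak_tbl(means)
  pres <- region_presence(tab)
  vp <- venn_partition(pres)

  # exhaustive tally: per compound, its exact region subset
  subsets <- tapply(pres$region, pres$compound,
                    function(r) paste(sort(unique(r)), collapse = "+"))
  for (i in seq_len(nrow(vp))) {
    expect_equal(vp$n_compounds[i], sum(subsets == vp$regions[i]),
                 info = vp$regions[i])
  }
  expect_equal(sum(vp$n_compounds), length(unique(pres$compound)))
  expect_equal(nrow(vp), 15)

  # singleton: one compound in one region only
  single <- tibble::tibble(compound = "x", region = "HY")
  vs <- venn_partition(single)
  expect_equal(vs$n_compounds[vs$regions == "HY"], 1)
  expect_equal(sum(vs$n_compounds), 1)

  # removing a region's samples never increases another region's presence
  tab_no_yt <- tab[tab$region != "YT", ]
  pres2 <- region_presence(tab_no_yt)
  for (r in c("HY", "LM", "SX")) {
    expect_true(all(pres2$compound[pres2$region == r] %in%
                      pres$compound[pres$region == r]))
  }
})

test_that("composition profiles are percentages of detected totals", {
  samples <- c("HY-S", "HY-P")
  means <- matrix(c(2, 4, 6, 12, 2, 6), 3, 2, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), samples))
  tab <- make_peak_tbl(means, chem_class = c("terpene", "terpene", "ester"))
  prof <- composition_profile(tab, "chem_class")
  # hand-computed: HY-S terpene (2+6)/10, ester 2/10; HY-P (4+12)/22, 6/22
  get <- function(s, cl) prof$percent[prof$sample == s & prof$chem_class == cl]
  expect_equal(get("HY-S", "terpene"), 80)
  expect_equal(get("HY-S", "ester"), 20)
  expect_equal(get("HY-P", "terpene"), 100 * 16 / 22)
  expect_equal(get("HY-P", "ester"), 100 * 6 / 22)

  # single shared category -> 100% everywhere
  one <- composition_profile(
    make_peak_tbl(means, chem_class = rep("ketone", 3)), "chem_class")
  expect_true(all(one$percent == 100))

  # equal concentrations in two classes -> 50/50
  eq <- make_peak_tbl(matrix(c(3, 3), 2, 1,
                             dimnames = list(c("a", "b"), "HY-S")),
                      chem_class = c("terpene", "ester"))
  expect_equal(sort(composition_profile(eq, "chem_class")$percent), c(50, 50))

  # invariant under uniform rescaling of a sample's concentrations
  tab_scaled <- dplyr::mutate(tab, mean_conc = mean_conc * 7.3)
  expect_equal(composition_profile(tab_scaled, "chem_class")$percent,
               prof$percent)

  # per-sample percentages sum to 100 on the real fixture
  fx <- composition_profile(fixture_peaks(), "aroma_category")
  sums <- tapply(fx$percent, fx$sample, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  # an all-censored sample has no denominator
  means_nd <- means
  means_nd[, 1] <- NA
  expect_error(composition_profile(make_peak_tbl(means_nd), "chem_class"),
               "zero total")
})
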