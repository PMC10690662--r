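test_that("region-set parsing distributes hemispheres and handles the empty marker", {
  expect_setequal(parse_region_set("AML + ATL R"), c("AML_R", "ATL_R"))
  expect_identical(parse_region_set("N"), character())
  expect_setequal(parse_region_set("AML L + ATL L + ATL R"),
                  c("AML_L", "ATL_L", "ATL_R"))
  expect_setequal(parse_region_set("AML R + AML L"), c("AML_R", "AML_L"))
  expect_setequal(parse_region_set("MC + LC + MP + LPr R"),
                  c("MC_R", "LC_R", "MP_R", "LPr_R"))
  expect_error(parse_region_set("XYZ R"), "XYZ")
  expect_error(parse_region_set("AML + ATL"), "hemisphere")
})

test_that("parse -> format -> parse round-trips every fixture cell", {
  co <- load_cohort_fixture()
  cells <- c(co$seeg, co$visual, co$spm, co$sipcom,
             co$surgery[co$surgery != "Idem"], co$mri_regions)
  for (cell in cells) {
    s <- parse_region_set(cell)
    expect_setequal(parse_region_set(format_region_set(s)), s)
  }
})

test_that("patient-level concordance is set intersection with the resection zone", {
  co <- load_cohort_fixture()
  expect_true(patient_concordant(co[co$patient_id == 17, ], "sipcom"))
  expect_false(patient_concordant(co[co$patient_id == 2, ], "sipcom"))
  # a method set equal to the RZ is always concordant
  rec <- co[1, ]
  rec$sipcom_set <- rec$rz
  expect_true(patient_concordant(rec, "sipcom"))
  # monotone: adding regions never flips true -> false
  rec2 <- co[co$patient_id == 17, ]
  rec2$sipcom_set <- list(union(rec2$sipcom_set[[1]], c("MO_L", "LP_L")))
  expect_true(patient_concordant(rec2, "sipcom"))
})

test_that("cohort and subgroup rates are exact count ratios", {
  co <- load_cohort_fixture()
  r <- cohort_rates(co, "sipcom")
  expect_identical(c(r$count, r$n), c(12L, 20L))
  expect_identical(r$rate, 12 / 20)
  expect_error(cohort_rates(co, "sipcom", rep(FALSE, nrow(co))), "empty")
  # a predicate subset works like the named ones
  r2 <- cohort_rates(co, "spm", function(rec) rec$engel_good)
  r3 <- cohort_rates(co, "spm", "engel_good")
  expect_identical(r2, r3)
})

test_that("micro-averaged recall/precision match an independent hand tally", {
  co <- load_cohort_fixture()
  # tally recomputed by explicit loops over the table rows
  tally <- function(col) {
    num <- 0L; den_m <- 0L; den_rz <- 0L
    for (i in seq_len(nrow(co))) {
      num <- num + length(intersect(co[[col]][[i]], co$rz[[i]]))
      den_m <- den_m + length(co[[col]][[i]])
      den_rz <- den_rz + length(co$rz[[i]])
    }
    c(num, den_rz, den_m)
  }
  t_spm <- tally("spm_set")
  rp_spm <- region_recall_precision(co, "spm")
  expect_equal(rp_spm$recall, t_spm[1] / t_spm[2])
  expect_equal(rp_spm$precision, t_spm[1] / t_spm[3])
  # frozen regression values from the packaged table
  expect_equal(rp_spm$recall, 12 / 47)
  expect_equal(rp_spm$precision, 12 / 14)
  rp_sip <- region_recall_precision(co, "sipcom")
  expect_equal(rp_sip$recall, 22 / 47)
  expect_equal(rp_sip$precision, 22 / 24)
  # degenerate cases
  co0 <- co; co0$spm_set <- replicate(nrow(co), character(), simplify = FALSE)
  rp0 <- region_recall_precision(co0, "spm")
  expect_equal(rp0$recall, 0)
  expect_true(is.na(rp0$precision))
  cop <- co; cop$spm_set <- cop$rz
  rpp <- region_recall_precision(cop, "spm")
  expect_equal(c(rpp$recall, rpp$precision), c(1, 1))
})

test_that("clusters are assigned every overlapping atlas region with fractions", {
  # toy atlas: two labels split 60/40 along x
  d <- c(10, 10, 10)
  atlas <- array(0L, d)
  atlas[1:6, , ] <- 1L; atlas[7:10, , ] <- 19L
  at <- data.frame(label_id = c(1L, 19L), region_code = c("AML", "AML"),
                   hemisphere = c("L", "R"))
  z <- array(0, d)
  z[2:6, 4, 4] <- 5                              # wholly inside label 1
  zm <- as_test_zmap(z)
  cfg <- detection_config(min_volume_ml = 0.004, erosion_voxels = 0L)
  tab <- assign_cluster_regions(extract_clusters(zm, cfg), atlas, at)
  expect_identical(tab$regions, "AML_L")
  expect_identical(tab$overlap_fractions, "1.000")
  # straddling cluster: 6 voxels in the left label, 4 in the right
  z2 <- array(0, d); z2[1:10, 5, 5] <- 5
  tab2 <- assign_cluster_regions(extract_clusters(as_test_zmap(z2), cfg), atlas, at)
  expect_setequal(attr(tab2, "region_sets")[[1]], c("AML_L", "AML_R"))
  expect_identical(tab2$overlap_fractions, "0.600 + 0.400")
  # cluster outside all labels warns and yields the empty set
  atlas0 <- array(0L, d)
  expect_warning(
    tab3 <- assign_cluster_regions(extract_clusters(zm, cfg), atlas0, at),
    "outside")
  expect_identical(attr(tab3, "region_sets")[[1]], character())
  # lattice mismatch is an error
  expect_error(assign_cluster_regions(extract_clusters(zm, cfg),
                                      array(0L, c(5, 5, 5)), at), "lattice")
})

test_that("false-positive summaries use the sample SD and flag n = 1", {
  s <- score_control_fp(c(0, 2, 4))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 2)                          # sample SD of {0,2,4}
  expect_equal(s$range, c(0, 4))
  empty_tabs <- list(data.frame(), data.frame(), data.frame())
  s0 <- score_control_fp(empty_tabs)
  expect_equal(c(s0$mean, s0$sd), c(0, 0))
  s1 <- score_control_fp(5)
  expect_true(s1$n1_flag)
  expect_equal(s1$sd, 0)
})

test_that("the evaluation report carries every method and subgroup", {
  ev <- evaluate_cohort()
  expect_s3_class(ev, "sipcom_evaluation")
  expect_setequal(unique(ev$rates$group),
                  c("all", "engel_good", "engel_poor", "mri_positive",
                    "mri_negative"))
  expect_equal(nrow(ev$rates), 15)
  expect_true(all(ev$rates$count <= ev$rates$n))
  expect_equal(ev$rates$rate, ev$rates$count / ev$rates$n)
})
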