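test_that("replicate averaging takes means over present values only", {
  tab <- data.frame(
    animal_id = paste0("a", 1:10),
    compound = "c1", dose = "high",
    time_point = rep(c("3 hr", "6 hr"), each = 5),
    p1 = c(7, 7, 7, 7, 7, 1, 2, 3, 4, 5),
    p2 = c(1, 2, NA, 4, 5, NA, NA, NA, NA, NA))
  out <- average_replicates(tab)
  expect_equal(out$p1, c(7, 3))
  expect_equal(out$p2[out$time_point == "3 hr"], 3)  # mean of {1,2,4,5}
  expect_true(is.na(out$p2[out$time_point == "6 hr"]))
  expect_equal(attr(out, "flagged_missing")$parameter, "p2")
  expect_equal(out$n_replicates, c(5L, 5L))
})

test_that("physiology normalization matches the linear-interpolation quantile convention", {
  cond <- data.frame(compound = paste0("c", 1:4), dose = "high",
                     time_point = "3 hr",
                     p1 = c(1, 2, 3, 4), p2 = c(10, 20, 15, 45))
  np <- normalize_physiology(cond)
  # independent oracle: center/IQR computed by hand with type-7 quantiles
  oracle <- function(x) (x - mean(x)) /
    unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
  expect_equal(unname(np$matrix[, "p1"]), oracle(c(1, 2, 3, 4)))
  expect_equal(unname(np$matrix[, "p2"]), oracle(c(10, 20, 15, 45)))
  # centering identity and invertibility from the stored manifest
  expect_equal(colMeans(np$matrix), c(p1 = 0, p2 = 0))
  back <- sweep(sweep(np$matrix, 2, np$iqr, "*"), 2, np$center, "+")
  expect_equal(unname(back[, "p1"]), cond$p1)

  cond$p3 <- 5
  expect_error(normalize_physiology(cond), "p3")
  expect_error(normalize_physiology(cond[1:3, c(1:3, 4, 5)]), "4 conditions")
})

test_that("vehicle-matched centering subtracts the matched control condition", {
  cond <- expand.grid(compound = c("c1", "c2"),
                      dose = c("control", "high"),
                      time_point = c("3 hr", "6 hr"),
                      stringsAsFactors = FALSE)
  set.seed(1)
  cond$p1 <- rnorm(nrow(cond), 10)
  cond$p2 <- rnorm(nrow(cond), 5)
  np <- normalize_physiology(cond, mode = "vehicle")
  i <- which(cond$compound == "c1" & cond$dose == "high" &
               cond$time_point == "6 hr")
  j <- which(cond$compound == "c1" & cond$dose == "control" &
               cond$time_point == "6 hr")
  expect_equal(unname(np$matrix[i, "p1"]),
               (cond$p1[i] - cond$p1[j]) / np$iqr[["p1"]])
})

test_that("curation ratio reproduces the project-level constant", {
  expect_equal(round(curation_threshold(5950, 17685), 3), 0.336)
  expect_equal(curation_threshold(1, 1), 1)
  expect_equal(curation_threshold(3, 12), 0.25)
  expect_error(curation_threshold(5, 0), "positive")
})

finding_row <- function(animal, dose, phenotype = "necrosis",
                        topography = "diffuse", grade = "minimal") {
  data.frame(animal_id = animal, compound = "c1", dose = dose,
             time_point = "29 day", tissue = "liver",
             phenotype = phenotype, topography = topography, grade = grade)
}

test_that("curation keeps compound-enriched tuples and drops the rest", {
  f <- rbind(
    do.call(rbind, lapply(1:3, function(i) finding_row(paste0("t", i), "high"))),
    do.call(rbind, lapply(1:4, function(i)
      finding_row(paste0("u", i), "high", phenotype = "swelling"))),
    do.call(rbind, lapply(1:2, function(i)
      finding_row(paste0("v", i), "control", phenotype = "swelling"))),
    finding_row("w1", "control", phenotype = "edema"))
  out <- curate_histopathology(f, r0 = 0.336)
  # 0/3 -> kept; 2/4 = 0.5 >= 0.336 -> dropped; vehicle-only -> dropped
  expect_setequal(unique(out$phenotype), "necrosis")
  expect_equal(attr(out, "vehicle_only")$phenotype, "edema")

  f2 <- rbind(finding_row("v1", "control"),
              do.call(rbind, lapply(1:10, function(i)
                finding_row(paste0("t", i), "high"))))
  out2 <- curate_histopathology(f2, r0 = 0.336)   # 1/10 < 0.336 -> kept
  expect_equal(nrow(out2), 11)

  # literal-text comparator is available and reverses the decision
  out3 <- curate_histopathology(f2, r0 = 0.336, keep_if = "gt")
  expect_equal(nrow(out3), 0)
})

test_that("curation retention is monotone in the ratio threshold", {
  sc <- small_cohort(seed = 17)
  lo <- curate_histopathology(sc$cohort$findings, 0.1)
  hi <- curate_histopathology(sc$cohort$findings, 0.5)
  key <- function(d) paste(d$animal_id, d$tissue, d$phenotype, d$topography,
                           d$grade)
  expect_true(all(key(lo) %in% key(hi)))
})

test_that("phenotype calls collapse topography and count supporting animals", {
  f <- rbind(finding_row("a1", "high", topography = "periportal"),
             finding_row("a1", "high", topography = "centrilobular"),
             finding_row("a2", "high"))
  calls <- call_condition_phenotypes(f)
  expect_equal(dim(calls), c(1L, 1L))
  expect_equal(unname(calls[1, 1]), 1L)
  expect_equal(unname(attr(calls, "support")[1, 1]), 2L)  # animals, not rows

  # one of five animals suffices; empty universe row stays zero
  calls2 <- call_condition_phenotypes(
    finding_row("a1", "high"),
    conditions = c(condition_id("c1", "high", "29 day"),
                   condition_id("c9", "low", "3 hr")))
  expect_equal(unname(calls2[, 1]), c(1L, 0L))

  # monotone: adding findings never clears a call
  more <- rbind(f, finding_row("a3", "high", phenotype = "swelling"))
  calls3 <- call_condition_phenotypes(more)
  expect_true(all(calls3[rownames(calls), colnames(calls)] >= calls))
})

test_that("expression normalization averages replicates then subtracts vehicles", {
  genes <- c("g1", "g2")
  samples <- data.frame(
    sample_id = paste0("s", 1:6),
    compound = "c1",
    dose = rep(c("high", "control"), each = 3),
    time_point = "29 day")
  mat <- cbind(c(2, 0), c(4, 0), c(6, 0),    # treated replicates
               c(1, 0), c(1, 0), c(1, 0))    # vehicle replicates
  dimnames(mat) <- list(genes, samples$sample_id)
  ed <- normalize_expression(mat, samples, "liver")
  expect_equal(unname(ed$delta["g1", ]), 3)   # mean(2,4,6) - 1
  expect_equal(unname(ed$delta["g2", ]), 0)

  expect_error(normalize_expression(mat[, 1:3], samples[1:3, ], "liver"),
               "vehicle")
})

test_that("food and body-weight deltas follow the treated-minus-vehicle convention", {
  s <- data.frame(compound = "c1",
                  dose = c("high", "high", "control", "control"),
                  time = c(1, 4, 1, 4),
                  value = c(20, NA, 25, 24))
  d <- normalize_food_bodyweight(s)
  expect_equal(d$delta, c(-5, NA))           # eats 5 g/day less; NA stays NA
  expect_equal(normalize_food_bodyweight(s, flip = TRUE)$delta[1], 5)

  same <- s; same$value <- c(25, 24, 25, 24)
  expect_equal(normalize_food_bodyweight(same)$delta, c(0, 0))

  bad <- rbind(s, data.frame(compound = "c1", dose = "high", time = 8,
                             value = 19))
  expect_error(normalize_food_bodyweight(bad), "grid")
})
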