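test_that("rank transform uses average ties", {
  expect_equal(rank_transform(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
  expect_equal(rank_transform(rep(7, 5)), rep(3, 5))
  set.seed(2)
  x <- rnorm(50)
  # sorting oracle
  expect_equal(rank_transform(x)[order(x)], seq_len(50))
})

test_that("compact letters encode exactly the non-significant pairs", {
  # letters must be consistent: two groups share a letter iff their pairwise
  # comparison is non-significant (exhaustive check on random matrices)
  for (s in 1:25) {
    set.seed(s)
    k <- sample(3:8, 1)
    sig <- matrix(FALSE, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      sig[i, j] <- sig[j, i] <- runif(1) < 0.4
    }
    lt <- compact_letters(sig)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      share <- any(strsplit(lt[i], "")[[1]] %in% strsplit(lt[j], "")[[1]])
      expect_equal(share, !sig[i, j],
                   label = sprintf("seed %d pair %d-%d", s, i, j))
    }
    expect_true(all(nchar(lt) >= 1))
  }
})

test_that("group assignment matches an independent studentized-range oracle", {
  spread <- seq(-2, 2, length.out = 20)
  vals <- list(hot = 30 + spread, warm = 29.9 + spread, cool = 10 + spread)
  pw <- planted_variable_world(vals)
  res <- classify_variable(pw$records, pw$stack, "BIO1", "high",
                           alpha = 0.05, min_records = 5)
  # oracle: Tukey-Kramer comparisons on pooled ranks from the studentized
  # range distribution, written against the published formulae
  df <- data.frame(taxon = pw$records$taxon_id)
  df$rank <- rank(unlist(vals))
  means <- tapply(df$rank, df$taxon, mean)
  ns <- tapply(df$rank, df$taxon, length)
  k <- length(means)
  mse <- sum(unlist(lapply(split(df$rank, df$taxon), function(v) {
    sum((v - mean(v))^2)
  }))) / (nrow(df) - k)
  taxa <- names(means)
  sig <- matrix(FALSE, k, k, dimnames = list(taxa, taxa))
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    p <- ptukey(q, k, nrow(df) - k, lower.tail = FALSE)
    sig[i, j] <- sig[j, i] <- p < 0.05
  }
  lt <- res$taxa$letters[match(taxa, res$taxa$taxon_id)]
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    share <- any(strsplit(lt[i], "")[[1]] %in% strsplit(lt[j], "")[[1]])
    expect_equal(share, !sig[i, j], label = paste(taxa[i], taxa[j]))
  }
  # planted structure: hot and warm share the top group, cool is below
  grp <- setNames(res$taxa$group, res$taxa$taxon_id)
  expect_equal(unname(grp[c("hot", "warm")]), c(1L, 1L))
  expect_gt(grp[["cool"]], 1L)
  expect_equal(res$excluded, character(0))
})

test_that("well-separated taxa fall into ordered groups 1/2/3", {
  set.seed(5)
  vals <- list(t1 = rnorm(25, 40, 1), t2 = rnorm(25, 30, 1),
               t3 = rnorm(25, 20, 1), t4 = rnorm(25, 10, 1))
  pw <- planted_variable_world(vals)
  res <- classify_variable(pw$records, pw$stack, "BIO1", "high")
  grp <- setNames(res$taxa$group, res$taxa$taxon_id)
  expect_equal(unname(grp[c("t1", "t2", "t3", "t4")]), c(1L, 2L, 3L, 3L))
  # direction flip makes the lowest-mean taxon group 1
  res_lo <- classify_variable(pw$records, pw$stack, "BIO1", "low")
  grp_lo <- setNames(res_lo$taxa$group, res_lo$taxa$taxon_id)
  expect_equal(unname(grp_lo[c("t4", "t3")]), c(1L, 2L))
})

test_that("group assignment is invariant to monotone transformation", {
  set.seed(8)
  vals <- list(a = rnorm(15, 5, 0.5), b = rnorm(15, 8, 0.5),
               c = rnorm(15, 12, 0.5))
  pw1 <- planted_variable_world(vals)
  pw2 <- planted_variable_world(lapply(vals, function(v) exp(v / 2)))
  r1 <- classify_variable(pw1$records, pw1$stack, "BIO1", "high")
  r2 <- classify_variable(pw2$records, pw2$stack, "BIO1", "high")
  expect_equal(r1$taxa[c("taxon_id", "group", "mean_rank")],
               r2$taxa[c("taxon_id", "group", "mean_rank")])
})

test_that("taxa with too few records are excluded from the ANOVA", {
  set.seed(4)
  vals <- list(a = rnorm(20, 10), b = rnorm(20, 20), tiny = rnorm(4, 30))
  pw <- planted_variable_world(vals)
  res <- classify_variable(pw$records, pw$stack, "BIO1", "high",
                           min_records = 5)
  expect_equal(res$excluded, "tiny")
  expect_false("tiny" %in% res$taxa$taxon_id)
  # identical distributions: single letter, both group 1, with a warning
  same <- planted_variable_world(list(u = rep(5, 10), v = rep(5, 10)))
  expect_warning(r0 <- classify_variable(same$records, same$stack, "BIO1",
                                         "high"),
                 "tied")
  expect_equal(r0$taxa$group, c(1L, 1L))
})

test_that("the four-variable classification recovers a planted specialist", {
  w <- get_world()
  cl <- clean_pipeline(w$records, w$countries, w$stack)
  hsd <- classify_all(cl$records, w$stack)
  expect_named(hsd, c("AMEANT", "TWETQ", "AP", "PWETQ"))
  # same records everywhere: identical exclusion lists
  excl <- lapply(hsd, `[[`, "excluded")
  expect_true(all(vapply(excl, identical, logical(1), excl[[1]])))
  # the hottest planted niche ends in group 1 for annual mean temperature,
  # the driest in group 1 for annual precipitation
  ni <- w$spec$niches
  hottest <- ni$taxon_id[which.max(ni$bio1_c)]
  driest <- ni$taxon_id[which.min(ni$bio12_c)]
  g_am <- setNames(hsd$AMEANT$taxa$group, hsd$AMEANT$taxa$taxon_id)
  g_ap <- setNames(hsd$AP$taxa$group, hsd$AP$taxa$taxon_id)
  expect_equal(unname(g_am[hottest]), 1L)
  expect_equal(unname(g_ap[driest]), 1L)
})

test_that("screening scores merge by the best-accession rule", {
  set.seed(3)
  vals <- list(a = rnorm(10, 30), b = rnorm(10, 20), c = rnorm(10, 10))
  pw <- planted_variable_world(vals)
  hsd <- list(AMEANT = classify_variable(pw$records, pw$stack, "BIO1", "high"))
  screening <- data.frame(
    taxon_id = c("a", "a", "a", "b", "c", "c"),
    accession_id = paste0("acc", 1:6),
    assay = c("salinity", "salinity", "salinity", "salinity", "dehydration",
              "dehydration"),
    score = c(3, 1, 4, 2, 4, 5))
  tol <- merge_screening(hsd, screening)
  expect_equal(tol$salinity[tol$taxon_id == "a"], "high")          # best is 1
  expect_equal(tol$salinity[tol$taxon_id == "b"], "intermediate")  # best is 2
  expect_equal(tol$dehydration[tol$taxon_id == "c"], "low")        # best >= 3
  expect_equal(tol$dehydration[tol$taxon_id == "a"], "nd")
  expect_equal(tol$salinity[tol$taxon_id == "c"], "nd")
  bad <- screening; bad$score[1] <- 7
  expect_error(merge_screening(hsd, bad), "Likert")
})

test_that("profile counts tally the high entries across the six columns", {
  # a taxon harsh for the seasonal-heat, annual-dry and seasonal-dry criteria
  # but nowhere else has a resilience profile of exactly three
  mk <- function(groups) {
    structure(list(taxa = data.frame(taxon_id = names(groups),
                                     group = unname(groups),
                                     stringsAsFactors = FALSE),
                   excluded = character(0)), class = "hsd_result")
  }
  hsd <- list(AMEANT = mk(c(x = 3L, y = 1L)), TWETQ = mk(c(x = 1L, y = 2L)),
              AP = mk(c(x = 1L, y = 3L)), PWETQ = mk(c(x = 1L, y = 3L)))
  screening <- data.frame(taxon_id = "x", accession_id = "a1",
                          assay = "salinity", score = 2)
  tol <- merge_screening(hsd, screening)
  xr <- tol[tol$taxon_id == "x", ]
  expect_equal(xr$profile_count, 3)
  expect_equal(xr$dehydration, "nd")
  expect_equal(xr$salinity, "intermediate")
  expect_equal(tol$profile_count[tol$taxon_id == "y"], 1)
})
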