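# Ecogeographic classification: record-level climate values are rank
# transformed over the pooled data, a one-way ANOVA with taxon as factor is
# followed by Tukey HSD pairwise comparisons (Tukey-Kramer under unbalanced
# sizes), a compact letter display is built, and taxa are assigned to three
# harshness groups: group 1 shares a letter with the taxon of most extreme
# mean rank, group 2 with the most extreme taxon not already in group 1, and
# group 3 is the remainder. Four variable/direction pairs define the harsh
# climates: permanently hot (high BIO1), seasonally hot (high BIO8),
# permanently dry (low BIO12), seasonally dry (low BIO16).

#' Rank transform with average ties
#'
#' @param values numeric vector (at least one finite value).
#' @return ranks 1..n, ties averaged.
#' @export
rank_transform <- function(values) {
  stopifnot(any(is.finite(values)))
  rank(values, ties.method = "average")
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: start from one letter covering all groups;
#' every significant pair splits each letter containing both; redundant
#' letters are absorbed. Two groups share a letter iff their comparison is
#' non-significant.
#'
#' @param signif logical matrix (TRUE = significantly different), with
#'   dimnames giving group labels; symmetric.
#' @return named character vector of letter strings per group.
#' @export
compact_letters <- function(signif) {
  labs <- rownames(signif)
  sets <- list(labs)
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (j <= i || !signif[i, j]) next
      a <- labs[i]; b <- labs[j]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another set
      keep <- rep(TRUE, length(new_sets))
      for (u in seq_along(new_sets)) {
        for (v in seq_along(new_sets)) {
          if (u != v && keep[u] && keep[v] &&
              all(new_sets[[u]] %in% new_sets[[v]]) &&
              !(all(new_sets[[v]] %in% new_sets[[u]]) && v > u)) {
            keep[u] <- FALSE
          }
        }
      }
      sets <- unique(new_sets[keep])
    }
  }
  # stable letter order: by the most extreme member each set contains
  letters_out <- stats::setNames(rep("", length(labs)), labs)
  ord <- order(vapply(sets, function(s) min(match(s, labs)), numeric(1)))
  sets <- sets[ord]
  for (k in seq_along(sets)) {
    l <- if (k <= 26) letters[k] else paste0(letters[(k - 1) %/% 26],
                                             letters[(k - 1) %% 26 + 1])
    for (g in sets[[k]]) letters_out[g] <- paste0(letters_out[g], l)
  }
  letters_out
}

#' Classify taxa into harshness groups for one climate variable
#'
#' Record-level values of `variable` are rank transformed over the pooled
#' records; a one-way ANOVA with taxon as factor is run on the ranks; Tukey
#' HSD pairwise comparisons at level `alpha` yield a compact letter display.
#' Group 1 = taxa sharing a letter with the extreme-mean taxon (highest mean
#' rank for `direction = "high"`, lowest for `"low"`); group 2 = taxa sharing
#' a letter with the most extreme taxon not already in group 1; group 3 =
#' everything else. Taxa with fewer than `min_records` records on data cells
#' are excluded and listed.
#'
#' @param records `presence_records`.
#' @param stack a `climate_stack`.
#' @param variable bioclim layer name (e.g. "BIO8").
#' @param direction "high" (harsh = hot) or "low" (harsh = dry).
#' @param alpha significance level (default 0.05).
#' @param min_records minimum records per taxon (default 5).
#' @return an `hsd_result`: data.frame `taxa` (taxon_id, mean_rank, n,
#'   letters, group), `anova` (F, p), `excluded`, plus metadata.
#' @export
classify_variable <- function(records, stack, variable, direction = "high",
                              alpha = 0.05, min_records = 5) {
  stopifnot(direction %in% c("high", "low"), variable %in% BIOCLIM_NAMES)
  vals <- raster_lookup(grid_raster(stack$grid, stack$layers[[variable]]),
                        records$lon, records$lat)
  ok <- !is.na(vals)
  df <- data.frame(taxon = records$taxon_id[ok], value = vals[ok],
                   stringsAsFactors = FALSE)
  cnt <- table(df$taxon)
  eligible <- names(cnt)[cnt >= min_records]
  excluded <- sort(setdiff(unique(records$taxon_id), eligible))
  if (length(eligible) < 2) stop("need >= 2 taxa with >= ", min_records,
                                 " records")
  df <- df[df$taxon %in% eligible, ]
  df$rank <- rank_transform(df$value)
  df$taxon <- factor(df$taxon)

  mean_rank <- tapply(df$rank, df$taxon, mean)
  n_tax <- tapply(df$rank, df$taxon, length)
  taxa_ord <- names(sort(mean_rank, decreasing = (direction == "high")))

  if (stats::var(df$rank) == 0) {
    warning("all ranks tied; every taxon assigned to group 1")
    letters_out <- stats::setNames(rep("a", length(eligible)), levels(df$taxon))
    grp <- stats::setNames(rep(1L, length(eligible)), levels(df$taxon))
    fstat <- NA_real_; pval <- NA_real_
  } else {
    fit <- stats::aov(rank ~ taxon, data = df)
    av <- summary(fit)[[1]]
    fstat <- av$`F value`[1]; pval <- av$`Pr(>F)`[1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$taxon
    labs <- levels(df$taxon)
    signif <- matrix(FALSE, length(labs), length(labs),
                     dimnames = list(labs, labs))
    pair <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    for (r in seq_len(nrow(tk))) {
      sig <- tk[r, "p adj"] < alpha
      signif[pair[r, 1], pair[r, 2]] <- sig
      signif[pair[r, 2], pair[r, 1]] <- sig
    }
    letters_out <- compact_letters(signif)
    shares <- function(a, b) {
      any(strsplit(letters_out[[a]], "")[[1]] %in%
            strsplit(letters_out[[b]], "")[[1]])
    }
    grp <- stats::setNames(rep(3L, length(labs)), labs)
    extreme1 <- taxa_ord[1]
    g1 <- labs[vapply(labs, shares, logical(1), b = extreme1)]
    grp[g1] <- 1L
    rest <- setdiff(taxa_ord, g1)
    if (length(rest)) {
      extreme2 <- rest[1]
      g2 <- setdiff(labs[vapply(labs, shares, logical(1), b = extreme2)], g1)
      grp[g2] <- 2L
    }
  }
  taxa <- data.frame(taxon_id = names(mean_rank),
                     mean_rank = as.numeric(mean_rank),
                     n = as.integer(n_tax),
                     letters = unname(letters_out[names(mean_rank)]),
                     group = unname(grp[names(mean_rank)]),
                     stringsAsFactors = FALSE)
  taxa <- taxa[order(match(taxa$taxon_id, taxa_ord)), ]
  rownames(taxa) <- NULL
  structure(list(variable = variable, direction = direction, alpha = alpha,
                 taxa = taxa, f_value = fstat, p_value = pval,
                 excluded = excluded),
            class = "hsd_result")
}

#' Classify taxa for the four harsh-climate definitions
#'
#' Permanently hot (high BIO1 / annual mean temperature), seasonally hot
#' (high BIO8 / wettest-quarter temperature), permanently dry (low BIO12 /
#' annual precipitation), seasonally dry (low BIO16 / wettest-quarter
#' precipitation).
#'
#' @param records `presence_records`.
#' @param stack a `climate_stack`.
#' @param alpha significance level (default 0.05).
#' @param min_records minimum records per taxon (default 5).
#' @return named list of four `hsd_result`s: `AMEANT`, `TWETQ`, `AP`, `PWETQ`.
#' @export
classify_all <- function(records, stack, alpha = 0.05, min_records = 5) {
  dirs <- c(AMEANT = "high", TWETQ = "high", AP = "low", PWETQ = "low")
  out <- lapply(names(dirs), function(nm) {
    classify_variable(records, stack, HARSHNESS_VARS[[nm]], dirs[[nm]],
                      alpha, min_records)
  })
  stats::setNames(out, names(dirs))
}

#' Merge climate groups and screening scores into the tolerance matrix
#'
#' Climate columns map group 1 to high, 2 to intermediate, 3 to low, and
#' excluded/absent taxa to nd. Assay columns use the best (minimum) accession
#' score per taxon: 1 = high, 2 = intermediate, 3-5 = low, unscreened = nd.
#' `profile_count` counts the "high" entries per taxon across the six
#' columns.
#'
#' @param hsd_results named list from [classify_all()].
#' @param screening screening-score data.frame (`taxon_id`, `assay`,
#'   `score`).
#' @param taxa optional character vector fixing the row set (default: taxa
#'   seen in either input).
#' @return data.frame: `taxon_id`, `AMEANT`, `TWETQ`, `AP`, `PWETQ`,
#'   `dehydration`, `salinity` (each high/intermediate/low/nd),
#'   `profile_count`.
#' @export
merge_screening <- function(hsd_results, screening, taxa = NULL) {
  if (!is.null(screening) && nrow(screening) &&
      !all(screening$score %in% 1:5)) {
    stop("screening score outside the 1-5 Likert scale")
  }
  lev <- c("high", "intermediate", "low")
  if (is.null(taxa)) {
    taxa <- sort(unique(c(unlist(lapply(hsd_results, function(h) {
      c(h$taxa$taxon_id, h$excluded)
    })), if (!is.null(screening)) screening$taxon_id)))
  }
  out <- data.frame(taxon_id = taxa, stringsAsFactors = FALSE)
  for (nm in names(hsd_results)) {
    h <- hsd_results[[nm]]
    col <- rep("nd", length(taxa))
    m <- match(taxa, h$taxa$taxon_id)
    col[!is.na(m)] <- lev[h$taxa$group[m[!is.na(m)]]]
    out[[nm]] <- col
  }
  for (assay in c("dehydration", "salinity")) {
    col <- rep("nd", length(taxa))
    if (!is.null(screening) && nrow(screening)) {
      sc <- screening[screening$assay == assay, ]
      if (nrow(sc)) {
        best <- tapply(sc$score, sc$taxon_id, min)
        m <- match(taxa, names(best))
        hit <- !is.na(m)
        col[hit] <- ifelse(best[m[hit]] == 1, "high",
                           ifelse(best[m[hit]] == 2, "intermediate", "low"))
      }
    }
    out[[assay]] <- col
  }
  cols <- c(names(hsd_results), "dehydration", "salinity")
  out$profile_count <- rowSums(out[cols] == "high")
  out
}
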