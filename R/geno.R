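#' Genotype matrices of biallelic dosages
#'
#' The central container: individuals x loci diploid dosages in `{0, 1, 2}`
#' (`NA` = missing), with one optional haploid marker carried on the female
#' mitochondria (dosages in `{0, 1}`). Dosage counts the "counted" allele at
#' each locus; [orient_alleles()] fixes which allele that is.
#'
#' @param geno integer matrix, individuals x loci, with rownames (unique
#'   individual ids) and colnames (unique locus ids).
#' @param loci data.frame with columns `locus`, `type` ("nuclear" or "mito"),
#'   and optionally `linkage_group`, `cM`; defaults to all-nuclear, unmapped.
#' @param site character vector of sampling-site labels per individual.
#' @param groups optional data.frame of group labels (columns such as
#'   `L1`, `L2`, `L3`) per individual.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, loci = NULL, site = NULL, groups = NULL) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)), !is.null(colnames(geno)))
  if (anyDuplicated(rownames(geno))) stop("duplicate individual ids")
  if (anyDuplicated(colnames(geno))) stop("duplicate locus ids")
  if (is.null(loci)) {
    loci <- data.frame(locus = colnames(geno), type = "nuclear",
                       linkage_group = NA_character_, cM = NA_real_,
                       stringsAsFactors = FALSE)
  }
  stopifnot(all(c("locus", "type") %in% names(loci)))
  if (!"linkage_group" %in% names(loci)) loci$linkage_group <- NA_character_
  if (!"cM" %in% names(loci)) loci$cM <- NA_real_
  loci <- loci[match(colnames(geno), loci$locus), , drop = FALSE]
  if (anyNA(loci$locus)) stop("loci metadata missing for some matrix columns")
  storage.mode(geno) <- "integer"
  ploidy <- ifelse(loci$type == "mito", 1L, 2L)
  bad <- sweep(geno, 2, ploidy, function(g, p) !is.na(g) & (g < 0L | g > p))
  if (any(bad)) stop("dosages out of bounds for locus ploidy")
  if (is.null(site)) site <- rep(NA_character_, nrow(geno))
  stopifnot(length(site) == nrow(geno))
  structure(
    list(geno = geno, loci = loci, site = as.character(site), groups = groups,
         orientation = rep("as_read", ncol(geno))),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d loci (%d mito)\n",
              nrow(x$geno), ncol(x$geno), sum(x$loci$type == "mito")))
  cat(sprintf("  missing: %.1f%% overall\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# internal: subset keeping metadata consistent
subset_gm <- function(gm, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(gm$geno))
  if (is.null(j)) j <- seq_len(ncol(gm$geno))
  structure(
    list(geno = gm$geno[i, j, drop = FALSE],
         loci = gm$loci[j, , drop = FALSE],
         site = gm$site[i],
         groups = if (is.null(gm$groups)) NULL else gm$groups[i, , drop = FALSE],
         orientation = gm$orientation[j]),
    class = "genotype_matrix"
  )
}

#' Per-locus ploidy vector (2 nuclear, 1 mito)
#' @param gm a `genotype_matrix`
#' @export
ploidy <- function(gm) ifelse(gm$loci$type == "mito", 1L, 2L)

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read and write genotype matrices
#'
#' Two on-disk dialects are supported. `"csv"`: a header row
#' `id,site,<locus1>,...` followed by one row per individual with integer
#' dosages (`NA` or empty = missing). `"structure"`: two rows per individual
#' (one per allele copy), columns `id`, optional `pop`, then one integer
#' allele code per locus with `-9` for missing; the counted allele is the
#' numerically larger code seen at each locus. Writing then reading either
#' dialect reproduces the matrix.
#'
#' @param path file path
#' @param dialect `"csv"` or `"structure"`
#' @param loci optional marker metadata data.frame (`locus`, `type`,
#'   `linkage_group`, `cM`) attached to the result
#' @return [read_genotypes()] returns a `genotype_matrix`.
#' @export
read_genotypes <- function(path, dialect = c("csv", "structure"), loci = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") read_genotypes_csv(path, loci)
  else read_genotypes_structure(path, loci)
}

read_genotypes_csv <- function(path, loci = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("genotype CSV needs a header and data rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("id", "site"))) {
    stop("genotype CSV header must start with 'id,site'")
  }
  locus_names <- header[-(1:2)]
  # field count by comma count: strsplit drops trailing empty fields
  ncomma <- lengths(regmatches(lines, gregexpr(",", lines, fixed = TRUE)))
  bad_row <- which(ncomma[-1] + 1L != length(header))
  if (length(bad_row)) {
    stop(sprintf("ragged row at line %d", bad_row[1] + 1L))
  }
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  rows <- lapply(rows, function(r) c(r, rep("", length(header) - length(r))))
  mat <- do.call(rbind, rows)
  ids <- mat[, 1]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate individual id at line %d",
                 which(duplicated(ids))[1] + 1L))
  }
  vals <- mat[, -(1:2), drop = FALSE]
  vals[vals %in% c("", "NA")] <- NA
  suppressWarnings(g <- matrix(as.integer(vals), nrow(vals), ncol(vals)))
  bad <- !is.na(vals) & is.na(g)
  if (any(bad)) {
    stop(sprintf("non-integer dosage at line %d",
                 which(rowSums(bad) > 0)[1] + 1L))
  }
  dimnames(g) <- list(ids, locus_names)
  genotype_matrix(g, loci = loci, site = mat[, 2])
}

read_genotypes_structure <- function(path, loci = NULL) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) %% 2 != 0) stop("STRUCTURE file must have two rows per individual")
  has_pop <- names(tab)[2] == "pop"
  first <- if (has_pop) 3L else 2L
  locus_names <- names(tab)[first:ncol(tab)]
  ids <- tab[[1]][seq(1, nrow(tab), by = 2)]
  ids2 <- tab[[1]][seq(2, nrow(tab), by = 2)]
  if (!identical(ids, ids2)) stop("STRUCTURE rows not paired by individual id")
  if (anyDuplicated(ids)) stop("duplicate individual ids in STRUCTURE file")
  al <- as.matrix(tab[, first:ncol(tab), drop = FALSE])
  storage.mode(al) <- "integer"
  al[al == -9L] <- NA_integer_
  a1 <- al[seq(1, nrow(al), by = 2), , drop = FALSE]
  a2 <- al[seq(2, nrow(al), by = 2), , drop = FALSE]
  g <- matrix(NA_integer_, length(ids), length(locus_names),
              dimnames = list(ids, locus_names))
  for (j in seq_along(locus_names)) {
    codes <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(codes) > 2) {
      stop(sprintf("locus '%s' has more than two allele codes", locus_names[j]))
    }
    counted <- if (length(codes)) max(codes) else NA_integer_
    haploid <- all(is.na(a2[, j]))
    d <- (a1[, j] == counted)
    if (!haploid) {
      d <- d + (a2[, j] == counted)
      d[is.na(a1[, j]) | is.na(a2[, j])] <- NA
    }
    g[, j] <- as.integer(d)
  }
  site <- if (has_pop) as.character(tab[[2]][seq(1, nrow(tab), by = 2)])
          else rep(NA_character_, length(ids))
  if (is.null(loci)) {
    haploid <- vapply(seq_along(locus_names), function(j) {
      all(is.na(a2[, j])) && !all(is.na(a1[, j]))
    }, logical(1))
    loci <- data.frame(locus = locus_names,
                       type = ifelse(haploid, "mito", "nuclear"),
                       linkage_group = NA_character_, cM = NA_real_,
                       stringsAsFactors = FALSE)
  }
  genotype_matrix(g, loci = loci, site = site)
}

#' @rdname read_genotypes
#' @param gm a `genotype_matrix`
#' @export
write_genotypes <- function(gm, path, dialect = c("csv", "structure")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    g <- gm$geno
    df <- data.frame(id = rownames(g), site = gm$site, g,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                       na = "NA")
  } else {
    p <- ploidy(gm)
    n <- nrow(gm$geno)
    a1 <- matrix(-9L, n, ncol(gm$geno))
    a2 <- matrix(-9L, n, ncol(gm$geno))
    for (j in seq_len(ncol(gm$geno))) {
      d <- gm$geno[, j]
      if (p[j] == 2L) {
        a1[, j] <- ifelse(is.na(d), -9L, ifelse(d >= 1L, 2L, 1L))
        a2[, j] <- ifelse(is.na(d), -9L, ifelse(d == 2L, 2L, 1L))
      } else {
        a1[, j] <- ifelse(is.na(d), -9L, ifelse(d == 1L, 2L, 1L))
        a2[, j] <- -9L
      }
    }
    rows <- matrix(NA_integer_, 2 * n, ncol(gm$geno))
    rows[seq(1, 2 * n, by = 2), ] <- a1
    rows[seq(2, 2 * n, by = 2), ] <- a2
    df <- data.frame(id = rep(rownames(gm$geno), each = 2),
                     pop = rep(ifelse(is.na(gm$site), "NA", gm$site), each = 2),
                     rows, stringsAsFactors = FALSE)
    names(df) <- c("id", "pop", colnames(gm$geno))
    utils::write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# QC filters
# ---------------------------------------------------------------------------

#' Resolve duplicated control individuals
#'
#' Genotyping controls duplicated between experiments are collapsed to a
#' single individual: the member of each declared pair with the least missing
#' data is retained. Per-pair genotype mismatch counts (ignoring loci missing
#' in either member) are recorded in the `dedupe_report` attribute as a
#' genotyping-accuracy diagnostic.
#'
#' @param gm a `genotype_matrix`
#' @param duplicate_pairs data.frame or 2-column matrix of individual id pairs
#' @return the deduplicated `genotype_matrix`
#' @export
dedupe_controls <- function(gm, duplicate_pairs) {
  pairs <- as.matrix(duplicate_pairs)
  stopifnot(ncol(pairs) == 2)
  unknown <- setdiff(c(pairs), rownames(gm$geno))
  if (length(unknown)) {
    stop(sprintf("duplicate pair references unknown id '%s'", unknown[1]))
  }
  drop <- character(0)
  report <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                       mismatches = NA_integer_, kept = NA_character_,
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    g1 <- gm$geno[pairs[k, 1], ]
    g2 <- gm$geno[pairs[k, 2], ]
    both <- !is.na(g1) & !is.na(g2)
    report$mismatches[k] <- sum(g1[both] != g2[both])
    keep <- if (sum(is.na(g1)) <= sum(is.na(g2))) 1L else 2L
    report$kept[k] <- pairs[k, keep]
    drop <- c(drop, pairs[k, 3L - keep])
  }
  out <- subset_gm(gm, i = !(rownames(gm$geno) %in% drop))
  attr(out, "dedupe_report") <- report
  out
}

#' Filter loci and individuals on missing data
#'
#' Loci with a missing fraction above `locus_max` over all individuals are
#' removed first; individuals with a missing fraction above `indiv_max` over
#' the retained loci are then removed. The order is fixed: loci, then
#' individuals.
#'
#' @param gm a `genotype_matrix`
#' @param locus_max maximum tolerated missing fraction per locus (default 0.10)
#' @param indiv_max maximum tolerated missing fraction per individual
#'   (default 0.30)
#' @return the filtered `genotype_matrix`
#' @export
filter_missing <- function(gm, locus_max = 0.10, indiv_max = 0.30) {
  stopifnot(locus_max >= 0, locus_max <= 1, indiv_max >= 0, indiv_max <= 1)
  keep_loc <- colMeans(is.na(gm$geno)) <= locus_max
  if (!any(keep_loc)) stop("filter_missing removed every locus")
  gm2 <- subset_gm(gm, j = keep_loc)
  keep_ind <- rowMeans(is.na(gm2$geno)) <= indiv_max
  subset_gm(gm2, i = keep_ind)
}

# ---------------------------------------------------------------------------
# Allele orientation
# ---------------------------------------------------------------------------

orientation_flips <- function(panel, lineageA, lineageB) {
  fA <- panel_freq(panel, lineageA)
  fB <- panel_freq(panel, lineageB)
  flip <- fB < fA
  tie <- fB == fA
  # tie-break: the lexicographically smaller allele label ("0") is counted
  flip[tie] <- TRUE
  list(flip = flip, tie = tie)
}

#' Orient alleles towards a focal lineage
#'
#' Recodes dosages so that, at every locus, the counted allele is the one more
#' frequent in `lineageB` (the focal lineage; here the Mediterranean
#' *M. galloprovincialis* side). Ties are broken towards the lexicographically
#' smaller allele label and flagged. Applying the orientation twice is the
#' identity.
#'
#' @param gm a `genotype_matrix` whose loci all appear in `panel`
#' @param panel a `lineage_panel` giving reference frequencies of the currently
#'   counted allele
#' @param lineageA,lineageB the two reference lineages; orientation is towards
#'   `lineageB`
#' @return `gm` with recoded dosages; `$orientation` is `"as_read"` or
#'   `"flipped"`, and tie-broken loci are listed in the `orientation_ties`
#'   attribute
#' @export
orient_alleles <- function(gm, panel, lineageA, lineageB) {
  miss <- setdiff(colnames(gm$geno), colnames(panel$freq))
  if (length(miss)) {
    stop(sprintf("locus '%s' absent from panel", miss[1]))
  }
  pan <- panel
  pan$freq <- pan$freq[, colnames(gm$geno), drop = FALSE]
  ofl <- orientation_flips(pan, lineageA, lineageB)
  already <- gm$orientation == "flipped"
  # panel frequencies refer to the currently counted allele, so the flip
  # decision is relative to the current state -- except at ties, where the
  # rule names an absolute target state ("0" counted), making re-orientation
  # a no-op
  flip_now <- ofl$flip
  flip_now[ofl$tie] <- !already[ofl$tie]
  p <- ploidy(gm)
  for (j in which(flip_now)) {
    gm$geno[, j] <- p[j] - gm$geno[, j]
  }
  gm$orientation <- ifelse(xor(already, flip_now), "flipped", "as_read")
  attr(gm, "orientation_ties") <- colnames(gm$geno)[ofl$tie]
  gm
}

#' @rdname orient_alleles
#' @return `orient_panel()` returns the panel with frequencies flipped by the
#'   same rule, so panel and genotypes refer to the same counted allele.
#' @export
orient_panel <- function(panel, lineageA, lineageB) {
  ofl <- orientation_flips(panel, lineageA, lineageB)
  panel$freq[, ofl$flip] <- 1 - panel$freq[, ofl$flip]
  attr(panel, "orientation_ties") <- colnames(panel$freq)[ofl$tie]
  panel
}
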