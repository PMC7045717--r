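#' Lineage allele-frequency panels
#'
#' A `lineage_panel` stores, for a set of named lineages arranged in a
#' hierarchy (species / allopatric lineage / locally introgressed
#' subpopulation, labelled L1/L2/L3), the frequency of the oriented allele at
#' each locus, together with the reference sample size behind each frequency.
#'
#' @param freq numeric matrix, lineages x loci, entries in \[0, 1\] (NA allowed
#'   for loci untyped in a lineage).
#' @param lineages data.frame with columns `lineage`, `level`, `parent`
#'   describing the hierarchy (a tree; the root's parent is NA).
#' @param n integer matrix of reference allele-copy counts, same shape as
#'   `freq`, or NULL when frequencies are simulated truth.
#' @return An object of class `lineage_panel`.
#' @export
lineage_panel <- function(freq, lineages, n = NULL) {
  stopifnot(is.matrix(freq), !is.null(rownames(freq)), !is.null(colnames(freq)))
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) {
    stop("panel frequencies must lie in [0, 1]")
  }
  stopifnot(all(c("lineage", "level", "parent") %in% names(lineages)))
  if (!setequal(rownames(freq), lineages$lineage)) {
    stop("rownames(freq) must match lineages$lineage")
  }
  # hierarchy must be a tree: every non-root parent is itself a lineage
  par <- lineages$parent[!is.na(lineages$parent)]
  if (!all(par %in% c(lineages$lineage, "root"))) {
    stop("lineage hierarchy is not a tree: unknown parent label")
  }
  if (!is.null(n)) stopifnot(identical(dim(n), dim(freq)))
  structure(
    list(freq = freq, lineages = lineages, n = n, loci = colnames(freq)),
    class = "lineage_panel"
  )
}

#' @export
print.lineage_panel <- function(x, ...) {
  cat(sprintf(
    "<lineage_panel> %d lineages x %d loci\n", nrow(x$freq), ncol(x$freq)
  ))
  print(x$lineages, row.names = FALSE)
  invisible(x)
}

#' Look up one lineage's frequency vector
#' @param panel a `lineage_panel`
#' @param lineage lineage label
#' @return named numeric vector over loci
#' @export
panel_freq <- function(panel, lineage) {
  if (!lineage %in% rownames(panel$freq)) {
    stop(sprintf("lineage '%s' not in panel", lineage))
  }
  panel$freq[lineage, ]
}

# Flatten a nested lineage tree into a parent table.
# A tree node is list(name =, F =, level = optional, children = list(...)).
flatten_lineage_tree <- function(tree) {
  out <- data.frame(
    lineage = character(), level = character(), parent = character(),
    F = numeric(), stringsAsFactors = FALSE
  )
  walk <- function(node, parent, depth) {
    stopifnot(!is.null(node$name))
    f <- if (is.null(node$F)) 0 else node$F
    if (f < 0 || f >= 1) stop("branch divergence F must lie in [0, 1)")
    lev <- if (!is.null(node$level)) node$level else paste0("L", depth)
    out[nrow(out) + 1L, ] <<- list(node$name, lev, parent, f)
    for (ch in node$children) walk(ch, node$name, depth + 1L)
  }
  for (ch in tree$children) walk(ch, "root", 1L)
  if (anyDuplicated(out$lineage)) stop("duplicate lineage names in tree")
  out
}

# One round of hierarchical Balding-Nichols sampling for a batch of loci:
# ancestral p ~ U(0.05, 0.95), child ~ Beta with mean parent and variance
# F * p * (1 - p) along every branch.
bn_sample_tree <- function(nodes, n_loci) {
  p_anc <- stats::runif(n_loci, 0.05, 0.95)
  freq <- matrix(NA_real_, nrow(nodes), n_loci,
                 dimnames = list(nodes$lineage, NULL))
  parent_freq <- function(lab) {
    if (lab == "root") p_anc else freq[lab, ]
  }
  # nodes are listed parent-before-child by construction
  for (i in seq_len(nrow(nodes))) {
    p <- parent_freq(nodes$parent[i])
    f <- nodes$F[i]
    if (f == 0) {
      freq[i, ] <- p
    } else {
      a <- p * (1 - f) / f
      b <- (1 - p) * (1 - f) / f
      freq[i, ] <- stats::rbeta(n_loci, a, b)
    }
  }
  freq
}

#' Simulate a panel of ancestry-informative marker frequencies
#'
#' Generates per-lineage allele frequencies by hierarchical Balding-Nichols
#' sampling along a lineage tree, retaining only loci whose allele-frequency
#' difference between two designated focal lineages reaches `afd_min`. This
#' emulates an ancestry-informative SNP panel: markers ascertained for high
#' differentiation between the lineages whose admixture is under study.
#'
#' @param cfg list with elements:
#'   \describe{
#'     \item{n_loci}{number of loci to generate (>= 1)}
#'     \item{lineage_tree}{nested list; each node has `name`, branch
#'       divergence `F` in \[0, 1), optional `level`, and `children`}
#'     \item{focal}{character(2), the two lineages whose AFD is screened}
#'     \item{afd_min}{minimum |f_A - f_B| for locus acceptance, in \[0, 1\]}
#'     \item{seed}{RNG seed (optional)}
#'   }
#' @param max_tries cap on total candidate loci drawn before giving up
#'   (default `1e4 * n_loci`); an unattainable `afd_min` fails explicitly.
#' @return a `lineage_panel` of simulated truth frequencies; loci are named
#'   `"L001"`, ... and carry no reference sample sizes.
#' @export
make_panel <- function(cfg, max_tries = NULL) {
  stopifnot(cfg$n_loci >= 1, cfg$afd_min >= 0, cfg$afd_min <= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nodes <- flatten_lineage_tree(cfg$lineage_tree)
  focal <- cfg$focal
  if (cfg$afd_min > 0) {
    stopifnot(length(focal) == 2, all(focal %in% nodes$lineage))
  }
  if (is.null(max_tries)) max_tries <- 1e4 * cfg$n_loci
  kept <- NULL
  tried <- 0L
  batch <- max(cfg$n_loci, 256L)
  while (is.null(kept) || ncol(kept) < cfg$n_loci) {
    if (tried >= max_tries) {
      stop(sprintf(
        paste0("make_panel: could not find %d loci with AFD >= %.3f between ",
               "'%s' and '%s' after %d candidates"),
        cfg$n_loci, cfg$afd_min, focal[1], focal[2], tried
      ))
    }
    f <- bn_sample_tree(nodes, batch)
    tried <- tried + batch
    ok <- if (cfg$afd_min > 0) {
      abs(f[focal[1], ] - f[focal[2], ]) >= cfg$afd_min
    } else rep(TRUE, batch)
    kept <- cbind(kept, f[, ok, drop = FALSE])
  }
  kept <- kept[, seq_len(cfg$n_loci), drop = FALSE]
  colnames(kept) <- sprintf("L%03d", seq_len(cfg$n_loci))
  lineage_panel(
    freq = kept,
    lineages = nodes[, c("lineage", "level", "parent")]
  )
}

#' Read / write a panel as TSV (`lineage, level, parent, locus, freq, n`)
#' @param panel a `lineage_panel`
#' @param path file path
#' @export
write_panel <- function(panel, path) {
  idx <- expand.grid(
    lineage = rownames(panel$freq), locus = colnames(panel$freq),
    stringsAsFactors = FALSE
  )
  meta <- panel$lineages[match(idx$lineage, panel$lineages$lineage), ]
  df <- data.frame(
    lineage = idx$lineage, level = meta$level, parent = meta$parent,
    locus = idx$locus,
    freq = panel$freq[cbind(idx$lineage, idx$locus)],
    n = if (is.null(panel$n)) NA_integer_ else panel$n[cbind(idx$lineage, idx$locus)]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lin <- unique(df$lineage)
  loc <- unique(df$locus)
  freq <- matrix(NA_real_, length(lin), length(loc),
                 dimnames = list(lin, loc))
  freq[cbind(df$lineage, df$locus)] <- df$freq
  nmat <- NULL
  if (!all(is.na(df$n))) {
    nmat <- matrix(NA_integer_, length(lin), length(loc),
                   dimnames = list(lin, loc))
    nmat[cbind(df$lineage, df$locus)] <- df$n
  }
  meta <- unique(df[, c("lineage", "level", "parent")])
  lineage_panel(freq, meta, n = nmat)
}
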