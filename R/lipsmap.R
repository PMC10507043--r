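# LiP-SMap interaction statistics: peptide filtering, differential abundance,
# protein-level interaction calls, and cross-species comparison via ortholog
# binarization, PCA and Ward-clustered functional-category heatmaps.

validate_peptide_table <- function(table) {
  need <- c("protein", "peptide", "group", "replicate", "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("peptide table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(table$intensity) | table$intensity <= 0)) {
    stop("intensities must be positive and finite")
  }
  key <- paste(table$protein, table$peptide, table$group, table$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (protein, peptide, group, replicate) records")
  }
  invisible(table)
}

#' Filter peptides by replicate coverage
#'
#' Retains a peptide only if it has at least `min_reps` intensity records in
#' every sample group present in the table (missing intensities are never
#' imputed).
#'
#' @param table Peptide table: data frame with columns `protein`, `peptide`,
#'   `group`, `replicate`, `intensity`.
#' @param min_reps Minimum records per group (default 3, boundary inclusive).
#' @return The filtered peptide table.
#' @export
filter_peptides <- function(table, min_reps = 3) {
  validate_peptide_table(table)
  groups <- unique(table$group)
  key <- paste(table$protein, table$peptide, sep = "\r")
  cnt <- table(key, table$group)
  ok_keys <- rownames(cnt)[apply(cnt[, groups, drop = FALSE] >= min_reps,
                                 1, all)]
  table[key %in% ok_keys, , drop = FALSE]
}

# vectorized two-sided equal-variance t-test on log2 intensities
two_group_t <- function(x_mean, x_var, x_n, y_mean, y_var, y_n) {
  df <- x_n + y_n - 2
  sp2 <- ((x_n - 1) * x_var + (y_n - 1) * y_var) / df
  se <- sqrt(sp2 * (1 / x_n + 1 / y_n))
  tstat <- (x_mean - y_mean) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero pooled variance: identical means -> p = 1; different means -> p = 0
  degen <- sp2 <= 0 | !is.finite(p)
  p[degen] <- ifelse(abs(x_mean - y_mean)[degen] < .Machine$double.eps^0.5,
                     1, 0)
  p
}

#' Peptide differential abundance between treatment groups
#'
#' For every peptide and every non-control group, computes the log2 fold
#' change (difference of group means of log2 intensities) and a two-sided
#' equal-variance t-test p-value, then Benjamini-Hochberg q-values across all
#' peptides within each comparison.
#'
#' @param table A filtered peptide table (see [filter_peptides()]).
#' @param control Name of the control group (default `"control"`).
#' @return Data frame with columns `protein`, `peptide`, `comparison`,
#'   `log2fc`, `p`, `q`.
#' @export
differential_abundance <- function(table, control = "control") {
  validate_peptide_table(table)
  if (!control %in% table$group) stop("control group '", control, "' absent")
  table$l2 <- log2(table$intensity)
  key <- paste(table$protein, table$peptide, sep = "\r")
  agg <- function(sub) {
    k <- paste(sub$protein, sub$peptide, sep = "\r")
    data.frame(key = unique(k),
               m = as.numeric(tapply(sub$l2, k, mean)[unique(k)]),
               v = as.numeric(tapply(sub$l2, k, stats::var)[unique(k)]),
               n = as.numeric(tapply(sub$l2, k, length)[unique(k)]))
  }
  ctrl <- agg(table[table$group == control, ])
  out <- list()
  for (g in setdiff(unique(table$group), control)) {
    trt <- agg(table[table$group == g, ])
    common <- intersect(trt$key, ctrl$key)
    it <- match(common, trt$key); ic <- match(common, ctrl$key)
    l2fc <- trt$m[it] - ctrl$m[ic]
    p <- two_group_t(trt$m[it], trt$v[it], trt$n[it],
                     ctrl$m[ic], ctrl$v[ic], ctrl$n[ic])
    q <- stats::p.adjust(p, method = "BH")
    pp <- strsplit(common, "\r", fixed = TRUE)
    out[[g]] <- data.frame(protein = vapply(pp, `[`, "", 1),
                           peptide = vapply(pp, `[`, "", 2),
                           comparison = g, log2fc = l2fc, p = p, q = q,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call protein-metabolite interactions
#'
#' A protein is called interacting with the metabolite at a treatment level
#' if at least one of its peptides has `q < q_threshold` (strict) in that
#' comparison.
#'
#' @param results Output of [differential_abundance()].
#' @param q_threshold Significance threshold on the BH q-value (default 0.01).
#' @return Data frame with columns `protein`, `comparison`, `interacting`,
#'   `n_significant_peptides`.
#' @export
call_interactions <- function(results, q_threshold = 0.01) {
  stopifnot(all(c("protein", "comparison", "q") %in% names(results)))
  sig <- results$q < q_threshold
  key <- paste(results$protein, results$comparison, sep = "\r")
  nsig <- tapply(sig, key, sum)
  keys <- names(nsig)
  pp <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(protein = vapply(pp, `[`, "", 1),
             comparison = vapply(pp, `[`, "", 2),
             interacting = as.numeric(nsig) >= 1,
             n_significant_peptides = as.numeric(nsig),
             stringsAsFactors = FALSE)
}

#' Binary ortholog interaction matrix across organisms
#'
#' Maps protein-level interaction calls onto orthologs, restricts to the
#' orthologs shared by (mapped in) all organisms, sets an entry to 1 when at
#' least one interacting protein of that organism/metabolite maps to the
#' ortholog, and drops all-zero columns.
#'
#' @param calls_by_organism Named list (organism -> data frame of
#'   [call_interactions()] output, with an added `metabolite` column or one
#'   metabolite per list element supplied via `metabolite`).
#' @param maps Named list (organism -> data frame with columns `protein`,
#'   `ortholog`, `categories`).
#' @return List with `matrix` (rows = organism/metabolite combination,
#'   columns = shared orthologs, 0/1) and `shared_orthologs`.
#' @export
ortholog_binary_matrix <- function(calls_by_organism, maps) {
  orgs <- names(calls_by_organism)
  miss <- setdiff(orgs, names(maps))
  if (length(miss)) stop("no ortholog map for organism(s): ",
                         paste(miss, collapse = ", "))
  shared <- Reduce(intersect, lapply(orgs, function(o) unique(maps[[o]]$ortholog)))
  rows <- list()
  for (o in orgs) {
    calls <- calls_by_organism[[o]]
    if (!"metabolite" %in% names(calls)) calls$metabolite <- "metabolite"
    mp <- maps[[o]]
    for (met in unique(calls$metabolite)) {
      sub <- calls[calls$metabolite == met & calls$interacting, ]
      hit_orth <- unique(mp$ortholog[mp$protein %in% sub$protein])
      rows[[paste(o, met, sep = "|")]] <- as.numeric(shared %in% hit_orth)
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- shared
  keep <- colSums(m) > 0
  list(matrix = m[, keep, drop = FALSE], shared_orthologs = shared)
}

#' PCA of binary interaction patterns
#'
#' Principal component analysis of the binary ortholog interaction matrix:
#' columns are mean-centered, not variance-scaled; components come from the
#' singular value decomposition.
#'
#' @param matrix Binary matrix from [ortholog_binary_matrix()].
#' @param n_components Number of components to report (default 2).
#' @return List with `scores` (rows x components), `variance_fraction`, and
#'   the `prcomp` fit.
#' @export
pca_interactions <- function(matrix, n_components = 2) {
  if (is.list(matrix) && !is.null(matrix$matrix)) matrix <- matrix$matrix
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    stop("PCA needs at least 2 rows and 2 columns")
  }
  fit <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  if (k < n_components) {
    warning("matrix rank below requested components; returning ", k)
  }
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       variance_fraction = vf[seq_len(k)], fit = fit)
}

#' Functional-category interaction fractions with Ward clustering
#'
#' Summarizes a binary ortholog interaction matrix into the fraction of
#' interacting orthologs per one-letter functional category and row condition,
#' computes Euclidean distances, and clusters rows (categories) and columns
#' (conditions) with the `ward.D2` agglomeration rule.
#'
#' @param matrix Binary matrix (or [ortholog_binary_matrix()] output).
#' @param map Data frame with columns `ortholog`, `categories` (string of
#'   one-letter category labels per ortholog).
#' @return List with `fractions` (categories x conditions), `row_order`,
#'   `col_order` (leaf orders), the two `hclust` objects, and `empty`
#'   (categories with no mapped ortholog, flagged fraction 0).
#' @export
category_heatmap <- function(matrix, map) {
  if (is.list(matrix) && !is.null(matrix$matrix)) matrix <- matrix$matrix
  stopifnot(all(c("ortholog", "categories") %in% names(map)))
  map <- map[!duplicated(map$ortholog), ]
  cats <- sort(unique(unlist(strsplit(map$categories, ""))))
  orth <- colnames(matrix)
  frac <- matrix(0, nrow = length(cats), ncol = nrow(matrix),
                 dimnames = list(cats, rownames(matrix)))
  empty <- logical(length(cats)); names(empty) <- cats
  for (k in seq_along(cats)) {
    members <- map$ortholog[grepl(cats[k], map$categories, fixed = TRUE)]
    members <- intersect(members, orth)
    if (length(members) == 0) { empty[k] <- TRUE; next }
    frac[k, ] <- rowSums(matrix[, members, drop = FALSE]) / length(members)
  }
  hr <- stats::hclust(stats::dist(frac, method = "euclidean"),
                      method = "ward.D2")
  hc <- stats::hclust(stats::dist(t(frac), method = "euclidean"),
                      method = "ward.D2")
  list(fractions = frac, row_order = rownames(frac)[hr$order],
       col_order = colnames(frac)[hc$order], row_hclust = hr,
       col_hclust = hc, empty = empty)
}

#' Overlap of significant peptides between replicate experiments
#'
#' For each q-value cutoff tier, counts peptides significant in either
#' experiment (the union), the mutual peptides (intersection), the mutual
#' fraction `|A n B| / |A u B|`, and the Pearson correlation of log2 fold
#' changes over the tier's peptides.
#'
#' @param resA,resB Differential results (see [differential_abundance()])
#'   sharing a peptide key space; single comparison each.
#' @param cutoffs q-value cutoffs (default 0.01 and 0.05).
#' @return Data frame with one row per cutoff: `cutoff`, `n_union`,
#'   `n_mutual`, `fraction`, `r_log2fc` (fraction is `NA` when the union is
#'   empty).
#' @export
replicate_overlap <- function(resA, resB, cutoffs = c(0.01, 0.05)) {
  keyA <- paste(resA$protein, resA$peptide, sep = "\r")
  keyB <- paste(resB$protein, resB$peptide, sep = "\r")
  out <- lapply(cutoffs, function(ct) {
    A <- keyA[resA$q < ct]
    B <- keyB[resB$q < ct]
    uni <- union(A, B)
    mut <- intersect(A, B)
    ia <- match(uni, keyA); ib <- match(uni, keyB)
    both <- !is.na(ia) & !is.na(ib)
    r <- if (sum(both) >= 3) stats::cor(resA$log2fc[ia[both]],
                                        resB$log2fc[ib[both]]) else NA_real_
    data.frame(cutoff = ct, n_union = length(uni), n_mutual = length(mut),
               fraction = if (length(uni)) length(mut) / length(uni)
                          else NA_real_,
               r_log2fc = r)
  })
  do.call(rbind, out)
}
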