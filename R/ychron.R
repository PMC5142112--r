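## Y-chromosome node dating: perfect-phylogeny construction from binary
## derived-allele matrices and rho-statistic age estimation with
## mutation-rate confidence propagation.

#' Y mutation-rate configuration
#'
#' @param mu per-site per-year point rate (default 0.76e-9).
#' @param mu_ci length-2 95% CI for the rate
#'   (default `c(0.67e-9, 0.86e-9)`).
#' @param L number of callable sites.
#' @export
y_rate_config <- function(mu = 0.76e-9, mu_ci = c(0.67e-9, 0.86e-9),
                          L = 1e7) {
  stopifnot(mu > 0, length(mu_ci) == 2, mu_ci[1] > 0,
            mu_ci[1] <= mu, mu <= mu_ci[2], L > 0)
  structure(list(mu = mu, mu_ci = mu_ci, L = L), class = "y_rate_config")
}

## recursive perfect-phylogeny builder; tipsets is a list site -> character
## vector of tips carrying the derived allele
build_pp_node <- function(tips, sites) {
  ## sites fully covering this clade map onto its stem; handled by caller
  inner <- sites[vapply(sites, function(s) length(s) < length(tips),
                        logical(1))]
  ## maximal derived sets define the children
  ord <- order(-lengths(inner))
  child_sets <- list()
  for (s in inner[ord]) {
    placed <- FALSE
    for (ci in seq_along(child_sets)) {
      cs <- child_sets[[ci]]
      if (all(s %in% cs)) { placed <- TRUE; break }
      if (any(s %in% cs))
        stop("matrix is incompatible with a perfect phylogeny: sites ",
             "grouping {", paste(s, collapse = ","), "} and {",
             paste(cs, collapse = ","), "} violate the four-gamete test")
    }
    if (!placed) child_sets[[length(child_sets) + 1L]] <- s
  }
  covered <- unlist(child_sets)
  for (t in setdiff(tips, covered))
    child_sets[[length(child_sets) + 1L]] <- t
  children <- lapply(child_sets, function(cs) {
    sub <- inner[vapply(inner, function(s) all(s %in% cs), logical(1))]
    stem <- sum(vapply(sub, function(s) length(s) == length(cs), logical(1)))
    kids <- if (length(cs) > 1L)
      build_pp_node(cs, sub[lengths(sub) < length(cs)])
    else list()
    list(tips = sort(cs), stem_mutations = stem, children = kids)
  })
  children
}

#' Build a perfect phylogeny from a binary derived-allele matrix
#'
#' The ancestral state of every site must be 0 (code derived alleles as 1,
#' e.g. by polarizing against an outgroup first). Under infinite sites the
#' tree is unique up to ordering; any pair of sites whose derived tip sets
#' overlap without nesting fails the four-gamete test and raises an error
#' naming the offending grouping.
#'
#' @param mat binary matrix, tips x sites, with tip row names.
#' @return An object of class `y_tree`: a nested node structure with
#'   per-branch derived-mutation counts, plus the tip names.
#' @export
build_perfect_phylogeny <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  vals <- unique(as.vector(mat))
  if (!all(vals %in% c(0L, 1L, 0, 1)))
    stop("matrix must be binary (0 = ancestral, 1 = derived)")
  tips <- rownames(mat)
  sites <- lapply(seq_len(ncol(mat)), function(j) tips[mat[, j] == 1])
  sites <- sites[lengths(sites) > 0L]
  root_stem <- sum(vapply(sites, function(s) length(s) == length(tips),
                          logical(1)))
  children <- build_pp_node(tips, sites[lengths(sites) < length(tips)])
  root <- list(tips = sort(tips), stem_mutations = root_stem,
               children = children)
  structure(list(root = root, tips = tips, n_sites = ncol(mat)),
            class = "y_tree")
}

## mean mutations from this node down to its descendant tips (the rho
## statistic), by weighted recursion over children
node_rho <- function(node) {
  if (!length(node$children)) return(0)
  num <- 0; den <- 0
  for (ch in node$children) {
    w <- length(ch$tips)
    num <- num + w * (node_rho(ch) + ch$stem_mutations)
    den <- den + w
  }
  num / den
}

## flatten the tree into a per-node table; node ids are preorder indices
flatten_nodes <- function(node, id = 1L, parent = NA_integer_) {
  row <- data.frame(node = id, parent = parent, n_tips = length(node$tips),
                    stem_mutations = node$stem_mutations,
                    rho = node_rho(node),
                    tips = paste(node$tips, collapse = ","),
                    stringsAsFactors = FALSE)
  out <- list(row)
  next_id <- id + 1L
  for (ch in node$children) {
    sub <- flatten_nodes(ch, next_id, id)
    out[[length(out) + 1L]] <- sub
    next_id <- next_id + nrow(sub)
  }
  do.call(rbind, out)
}

#' @export
print.y_tree <- function(x, ...) {
  cat("y_tree:", length(x$tips), "tips,", x$n_sites, "sites; root rho =",
      round(node_rho(x$root), 3), "\n")
  invisible(x)
}

#' Export a Y tree to newick with branch lengths = mutation counts
#' @param tree a `y_tree`.
#' @param path optional output file; when `NULL` the newick string is
#'   returned.
#' @export
y_tree_newick <- function(tree, path = NULL) {
  rec <- function(node) {
    if (!length(node$children) && length(node$tips) == 1L)
      return(paste0(node$tips, ":", node$stem_mutations))
    inner <- paste(vapply(node$children, rec, ""), collapse = ",")
    paste0("(", inner, "):", node$stem_mutations)
  }
  nwk <- paste0(rec(tree$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

## locate a node by preorder id
find_node <- function(node, id, cur = 1L) {
  if (cur == id) return(list(node = node, next_id = cur + 1L))
  nxt <- cur + 1L
  for (ch in node$children) {
    r <- find_node(ch, id, nxt)
    if (!is.null(r$node)) return(r)
    nxt <- r$next_id
  }
  list(node = NULL, next_id = nxt)
}

#' rho-statistic age of a tree node
#'
#' `rho` is the mean number of derived mutations from the node to its
#' descendant tips; the age is `rho / (mu * L)` years. Three confidence
#' intervals are reported: the rho sampling CI (Saillard-style,
#' `SE^2 = rho / n_tips` under a star approximation), the mutation-rate CI
#' (endpoints `rho / (mu_upper * L)` and `rho / (mu_lower * L)`, exact), and
#' a combined CI whose relative half-widths add in quadrature.
#'
#' @param tree a `y_tree` from [build_perfect_phylogeny()].
#' @param node preorder node id (1 = root; see [clade_rho_report()]).
#' @param rates a [y_rate_config()].
#' @return list: rho, n_tips, age_years, ci_sampling, ci_rate, ci_combined.
#' @export
rho_age <- function(tree, node = 1L, rates = y_rate_config()) {
  nd <- find_node(tree$root, node)$node
  if (is.null(nd)) stop("no node with id ", node)
  if (!length(nd$tips)) stop("node has no descendant tips")
  rho <- node_rho(nd)
  mul <- rates$mu * rates$L
  if (mul == 0) stop("mu * L must be positive")
  age <- rho / mul
  se_rho <- sqrt(rho / length(nd$tips))
  ci_samp <- c(max(0, rho - 1.96 * se_rho), rho + 1.96 * se_rho) / mul
  ci_rate <- c(rho / (rates$mu_ci[2] * rates$L),
               rho / (rates$mu_ci[1] * rates$L))
  rel_samp <- if (age > 0) (ci_samp[2] - ci_samp[1]) / (2 * age) else 0
  rel_rate <- if (age > 0) (ci_rate[2] - ci_rate[1]) / (2 * age) else 0
  rel <- sqrt(rel_samp^2 + rel_rate^2)
  list(rho = rho, n_tips = length(nd$tips), age_years = age,
       ci_sampling = ci_samp, ci_rate = ci_rate,
       ci_combined = c(max(0, age * (1 - rel)), age * (1 + rel)))
}

#' Per-node rho dating report
#'
#' @param tree a `y_tree`.
#' @param rates a [y_rate_config()].
#' @param internal_only drop single-tip nodes (default TRUE).
#' @return data.frame: node, parent, n_tips, rho, age_years, CI columns,
#'   tips.
#' @export
clade_rho_report <- function(tree, rates = y_rate_config(),
                             internal_only = TRUE) {
  tab <- flatten_nodes(tree$root)
  if (internal_only) tab <- tab[tab$n_tips > 1L | tab$node == 1L, ]
  ages <- lapply(tab$node, function(id) rho_age(tree, id, rates))
  tab$age_years <- vapply(ages, `[[`, numeric(1), "age_years")
  tab$ci_sampling_lo <- vapply(ages, function(a) a$ci_sampling[1], numeric(1))
  tab$ci_sampling_hi <- vapply(ages, function(a) a$ci_sampling[2], numeric(1))
  tab$ci_rate_lo <- vapply(ages, function(a) a$ci_rate[1], numeric(1))
  tab$ci_rate_hi <- vapply(ages, function(a) a$ci_rate[2], numeric(1))
  tab$ci_combined_lo <- vapply(ages, function(a) a$ci_combined[1], numeric(1))
  tab$ci_combined_hi <- vapply(ages, function(a) a$ci_combined[2], numeric(1))
  rownames(tab) <- NULL
  tab
}

#' Read a tips x sites binary matrix from TSV
#' @param path TSV with a header of site ids and tip ids in the first
#'   column.
#' @export
read_y_matrix <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  as.matrix(d)
}
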