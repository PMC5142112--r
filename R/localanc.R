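## Windowed PCA-based local-ancestry assignment (PCAdmix-style): project
## haplotypes window by window onto reference PCs, call ancestry by a
## two-class Gaussian posterior, and merge calls into diploid masks.

#' Partition chromosomes into genetic-distance windows
#'
#' Contiguous windows of `size_cm` centimorgans starting at each
#' chromosome's first map anchor; the last window may be short. A
#' chromosome absent from the map (or with zero genetic length) yields zero
#' windows.
#'
#' @param map a [genetic_map()].
#' @param chroms chromosome names (default: all in the map).
#' @param size_cm window size in cM (default 1).
#' @return data.frame: chrom, window, start_cm, end_cm, start_bp, end_bp
#'   (bp spans 0-based half-open).
#' @export
window_partition <- function(map, chroms = names(map$chrom), size_cm = 1) {
  stopifnot(size_cm > 0)
  out <- list()
  for (ch in chroms) {
    d <- map$chrom[[ch]]
    if (is.null(d)) next
    cmin <- min(d$cm); cmax <- max(d$cm)
    if (cmax <= cmin) next
    lo <- seq(cmin, cmax, by = size_cm)
    if (lo[length(lo)] >= cmax) lo <- lo[-length(lo)]
    hi <- pmin(lo + size_cm, cmax)
    ## half-open bp spans sharing their boundaries, so windows tile exactly
    start_bp <- round(interpolate_bp(map, ch, lo)) - 1
    end_bp <- c(start_bp[-1], round(interpolate_bp(map, ch, cmax)))
    out[[ch]] <- data.frame(
      chrom = ch, window = seq_along(lo), start_cm = lo, end_cm = hi,
      start_bp = start_bp, end_bp = end_bp,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), window = integer(),
                      start_cm = numeric(), end_cm = numeric(),
                      start_bp = numeric(), end_bp = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

## rows of panel variants falling in one window (cm in [start, end); the
## last window of a chromosome is closed on the right)
window_rows <- function(panel, win, last_end) {
  cm <- panel$variants$cm
  hit <- panel$variants$chrom == win$chrom & !is.na(cm) &
    cm >= win$start_cm &
    (cm < win$end_cm | (win$end_cm == last_end & cm <= win$end_cm))
  which(hit)
}

## log-density of a multivariate normal with ridge-regularized covariance
ldmvn <- function(x, mu, sigma) {
  k <- length(mu)
  ridge <- diag(k) * (1e-6 * mean(diag(sigma)) + 1e-12)
  ch <- chol(sigma + ridge)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(ch))) - 0.5 * k * log(2 * pi)
}

#' Fit per-window reference PCA models for local-ancestry calling
#'
#' For each window, reference haplotypes of the two ancestries are projected
#' onto their leading principal components; each ancestry is summarized by
#' the mean and covariance of its projected haplotypes. Windows with fewer
#' than `min_snps` SNPs, or fewer than 2 reference haplotypes per ancestry,
#' are marked unassignable.
#'
#' @param panel a phased [genotype_panel()] with map coordinates attached.
#' @param windows window table from [window_partition()].
#' @param refs named character vector of length 2 mapping short ancestry
#'   labels to reference population names, e.g.
#'   `c(A = "African", E = "Eurasian")`.
#' @param n_components number of PCs (default 2).
#' @param min_snps minimum SNPs per usable window (default 2).
#' @return An object of class `ancestry_model`.
#' @export
fit_reference_pca <- function(panel, windows, refs, n_components = 2,
                              min_snps = 2) {
  stopifnot(length(refs) == 2, !is.null(names(refs)))
  if (is.null(panel$hap)) stop("reference panel must be phased")
  ids <- lapply(refs, function(pp) panel$samples$id[panel$samples$pop == pp])
  if (any(lengths(ids) < 1))
    stop("missing reference samples for: ",
         paste(refs[lengths(ids) < 1], collapse = ", "))
  cols <- lapply(ids, function(x) hap_columns(panel, x))
  if (any(lengths(cols) < 2))
    stop("need >= 2 reference haplotypes per ancestry")
  last_end <- tapply(windows$end_cm, windows$chrom, max)
  fits <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    rows <- window_rows(panel, windows[i, ], last_end[[windows$chrom[i]]])
    if (length(rows) < min_snps) next
    H <- t(panel$hap[rows, c(cols[[1]], cols[[2]]), drop = FALSE])
    H[is.na(H)] <- 0L
    k <- min(n_components, ncol(H), nrow(H) - 1L)
    pc <- stats::prcomp(H, center = TRUE, scale. = FALSE, rank. = k)
    grp <- rep(names(refs), c(length(cols[[1]]), length(cols[[2]])))
    sc <- pc$x[, seq_len(k), drop = FALSE]
    summ <- lapply(names(refs), function(g) {
      s <- sc[grp == g, , drop = FALSE]
      cv <- if (nrow(s) > 1) stats::cov(s) else matrix(0, k, k)
      list(mean = colMeans(s), cov = cv)
    })
    names(summ) <- names(refs)
    fits[[i]] <- list(rows = rows, center = pc$center,
                      rotation = pc$rotation[, seq_len(k), drop = FALSE],
                      classes = summ)
  }
  structure(list(windows = windows, fits = fits, refs = refs,
                 n_components = n_components),
            class = "ancestry_model")
}

#' Call haplotype ancestry per window
#'
#' Projects each query haplotype onto each window's reference PCs and
#' assigns the posterior of the two ancestry classes under equal-prior
#' Gaussian likelihoods. A call is `assigned` only when the larger posterior
#' exceeds `threshold` (default 0.9); windows marked unassignable during
#' fitting yield posteriors of 0.5 and are never assigned.
#'
#' @param model an [fit_reference_pca()] result.
#' @param panel a phased [genotype_panel()] holding the query samples.
#' @param query sample ids to call.
#' @param threshold posterior threshold for assignment (default 0.9).
#' @return data.frame of class `ancestry_calls`: sample, haplotype, chrom,
#'   window, start_bp, end_bp, posterior per label, label, posterior,
#'   assigned.
#' @export
call_ancestry <- function(model, panel, query, threshold = 0.9) {
  if (is.null(panel$hap)) stop("query panel must be phased")
  labs <- names(model$refs)
  cols <- hap_columns(panel, query)
  hap_sample <- rep(query, each = 2L)
  hap_no <- rep(c(1L, 2L), length(query))
  out <- list()
  for (i in seq_len(nrow(model$windows))) {
    win <- model$windows[i, ]
    fit <- model$fits[[i]]
    n_h <- length(cols)
    if (is.null(fit)) {
      p1 <- rep(0.5, n_h)
    } else {
      Q <- t(panel$hap[fit$rows, cols, drop = FALSE])
      Q[is.na(Q)] <- 0L
      sc <- sweep(Q, 2L, fit$center) %*% fit$rotation
      ll <- vapply(labs, function(g)
        apply(sc, 1L, function(x)
          ldmvn(x, fit$classes[[g]]$mean, fit$classes[[g]]$cov)),
        numeric(n_h))
      if (n_h == 1L) ll <- matrix(ll, nrow = 1L)
      p1 <- 1 / (1 + exp(ll[, 2L] - ll[, 1L]))
    }
    post <- pmax(p1, 1 - p1)
    out[[i]] <- data.frame(
      sample = hap_sample, haplotype = hap_no, chrom = win$chrom,
      window = win$window, start_bp = win$start_bp, end_bp = win$end_bp,
      post_1 = p1, post_2 = 1 - p1,
      label = ifelse(p1 >= 0.5, labs[1], labs[2]),
      posterior = post,
      assigned = !is.null(fit) & post > threshold,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out)
  names(calls)[names(calls) == "post_1"] <- paste0("post_", labs[1])
  names(calls)[names(calls) == "post_2"] <- paste0("post_", labs[2])
  calls <- calls[order(calls$sample, calls$haplotype, calls$chrom,
                       calls$window), ]
  rownames(calls) <- NULL
  class(calls) <- c("ancestry_calls", "data.frame")
  calls
}

#' Build diploid ancestry masks from haplotype calls
#'
#' Combines the two haplotype calls of each sample per window into a diploid
#' class (e.g. `AA`, `AE`, `EE`; `unassigned` when either haplotype is not
#' confidently assigned) and merges consecutive same-class windows into
#' segments.
#'
#' @param calls an `ancestry_calls` data.frame from [call_ancestry()].
#' @return data.frame of class `ancestry_mask`: sample, chrom, start, end
#'   (bp, 0-based half-open), class, n_windows, mean_posterior.
#' @export
build_masks <- function(calls) {
  segs <- list()
  for (sid in unique(calls$sample)) {
    for (ch in unique(calls$chrom[calls$sample == sid])) {
      cc <- calls[calls$sample == sid & calls$chrom == ch, ]
      h1 <- cc[cc$haplotype == 1L, ]; h2 <- cc[cc$haplotype == 2L, ]
      if (!all(h1$window == h2$window))
        stop("haplotypes of ", sid, " called on different windows")
      cls <- ifelse(h1$assigned & h2$assigned,
                    paste0(pmin(h1$label, h2$label),
                           pmax(h1$label, h2$label)),
                    "unassigned")
      post <- (h1$posterior + h2$posterior) / 2
      r <- rle(cls)
      hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
      segs[[length(segs) + 1L]] <- data.frame(
        sample = sid, chrom = ch,
        start = h1$start_bp[lo], end = h1$end_bp[hi],
        class = r$values, n_windows = r$lengths,
        mean_posterior = vapply(seq_along(lo), function(j)
          mean(post[lo[j]:hi[j]]), numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  mask <- do.call(rbind, segs)
  rownames(mask) <- NULL
  class(mask) <- c("ancestry_mask", "data.frame")
  mask
}

#' Diploid ancestry mask from simulation truth tracts
#'
#' Overlays the two haplotype truth tracts of each sample and labels every
#' resulting segment with its diploid class; ancestries not named in
#' `labels` become `unassigned`. Useful as the exact reference against which
#' PCA-based masks are evaluated, and to feed segment-heterozygosity
#' analyses with perfect masks.
#'
#' @param truth the `truth` element of a [simulate_panel()] result.
#' @param labels named character vector mapping short labels to ancestry
#'   names, e.g. `c(A = "African", E = "Eurasian")`.
#' @return An `ancestry_mask` data.frame.
#' @export
truth_to_mask <- function(truth, labels) {
  tr <- truth$tracts
  inv <- stats::setNames(names(labels), labels)
  segs <- list()
  for (sid in unique(tr$sample)) {
    for (ch in unique(tr$chrom[tr$sample == sid])) {
      t1 <- tr[tr$sample == sid & tr$chrom == ch & tr$haplotype == 1L, ]
      t2 <- tr[tr$sample == sid & tr$chrom == ch & tr$haplotype == 2L, ]
      brk <- sort(unique(c(t1$start, t1$end, t2$start, t2$end)))
      lo <- brk[-length(brk)]; hi <- brk[-1]
      anc_at <- function(tt, x)
        tt$ancestry[findInterval(x, tt$start)]
      a1 <- unname(inv[anc_at(t1, lo)]); a2 <- unname(inv[anc_at(t2, lo)])
      cls <- ifelse(is.na(a1) | is.na(a2), "unassigned",
                    paste0(pmin(a1, a2), pmax(a1, a2)))
      r <- rle(cls)
      hiw <- cumsum(r$lengths); low <- hiw - r$lengths + 1L
      segs[[length(segs) + 1L]] <- data.frame(
        sample = sid, chrom = ch, start = lo[low], end = hi[hiw],
        class = r$values, n_windows = r$lengths,
        mean_posterior = 1, stringsAsFactors = FALSE)
    }
  }
  mask <- do.call(rbind, segs)
  rownames(mask) <- NULL
  class(mask) <- c("ancestry_mask", "data.frame")
  mask
}

#' Mask out genotypes falling in segments of a given diploid class
#'
#' Sets to missing, per sample, every variant lying inside that sample's
#' segments of class `drop_class` (segment coordinates 0-based half-open;
#' variant positions 1-based).
#'
#' @param panel a [genotype_panel()].
#' @param mask an `ancestry_mask`.
#' @param drop_class diploid class to remove (e.g. `"EE"`).
#' @return The masked [genotype_panel()].
#' @export
apply_negative_mask <- function(panel, mask, drop_class) {
  mm <- mask[mask$class == drop_class, , drop = FALSE]
  for (i in seq_len(nrow(mm))) {
    si <- match(mm$sample[i], panel$samples$id)
    if (is.na(si)) next
    hit <- panel$variants$chrom == mm$chrom[i] &
      (panel$variants$pos - 1L) >= mm$start[i] &
      (panel$variants$pos - 1L) < mm$end[i]
    panel$geno[hit, si] <- NA_integer_
    if (!is.null(panel$hap))
      panel$hap[hit, c(2L * si - 1L, 2L * si)] <- NA_integer_
  }
  panel
}
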