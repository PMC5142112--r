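#' Construct a genotype panel
#'
#' The central data container of the package: a set of biallelic variants
#' typed in a set of samples with population labels. Genotypes are stored as
#' alt-allele dosages (0/1/2, `NA` for missing). If the data are phased, the
#' per-haplotype allele matrix (0/1) is carried alongside and the dosage
#' matrix must equal the sum of the two haplotype columns of every sample.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `aa` (ancestral allele) and `cm` (genetic-map
#'   position; usually filled later by [attach_map()]).
#' @param samples data.frame with columns `id` and `pop`.
#' @param geno integer matrix, variants x samples, values 0/1/2/`NA`.
#' @param hap optional integer matrix, variants x (2 * samples), values 0/1;
#'   haplotype columns of sample i are `2i-1` and `2i`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(variants, samples, geno, hap = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            all(c("id", "pop") %in% names(samples)))
  if (is.null(variants$aa)) variants$aa <- NA_character_
  if (is.null(variants$cm)) variants$cm <- NA_real_
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(variants) || ncol(geno) != nrow(samples))
    stop("geno must be variants x samples")
  if (anyDuplicated(samples$id)) stop("duplicate sample id")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(hap)) {
    hap <- as.matrix(hap)
    storage.mode(hap) <- "integer"
    if (nrow(hap) != nrow(geno) || ncol(hap) != 2L * ncol(geno))
      stop("hap must be variants x 2*samples")
    d <- hap[, seq(1L, ncol(hap), 2L), drop = FALSE] +
      hap[, seq(2L, ncol(hap), 2L), drop = FALSE]
    ok <- is.na(geno) | (d == geno)
    if (!all(ok, na.rm = TRUE)) stop("dosage must equal haplotype sum")
    colnames(hap) <- paste0(rep(samples$id, each = 2L), "_", c(1L, 2L))
  }
  colnames(geno) <- samples$id
  structure(list(variants = variants, samples = samples,
                 geno = geno, hap = hap),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$variants), "variants x",
      nrow(x$samples), "samples",
      if (!is.null(x$hap)) "(phased)" else "(unphased)", "\n")
  cat("  populations:",
      paste(sprintf("%s(%d)", names(table(x$samples$pop)),
                    table(x$samples$pop)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(nrow(x$variants), nrow(x$samples))

#' Subset a genotype panel by variant and/or sample index
#'
#' @param panel a [genotype_panel()].
#' @param variants,samples index vectors (integer or logical); `NULL` keeps all.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  vi <- if (is.null(variants)) seq_len(nrow(panel$variants)) else
    seq_len(nrow(panel$variants))[variants]
  si <- if (is.null(samples)) seq_len(nrow(panel$samples)) else
    seq_len(nrow(panel$samples))[samples]
  hap <- NULL
  if (!is.null(panel$hap)) {
    hcols <- as.vector(rbind(2L * si - 1L, 2L * si))
    hap <- panel$hap[vi, hcols, drop = FALSE]
  }
  genotype_panel(panel$variants[vi, , drop = FALSE],
                 panel$samples[si, , drop = FALSE],
                 panel$geno[vi, si, drop = FALSE], hap)
}

sample_index <- function(panel, ids) {
  i <- match(ids, panel$samples$id)
  if (anyNA(i)) stop("unknown sample id: ", paste(ids[is.na(i)], collapse = ", "))
  i
}

#' Haplotype columns of given samples
#' @keywords internal
hap_columns <- function(panel, ids) {
  if (is.null(panel$hap)) stop("panel is not phased")
  i <- sample_index(panel, ids)
  as.vector(rbind(2L * i - 1L, 2L * i))
}

## ---------------------------------------------------------------- VCF I/O --

#' Read a VCF file into a genotype panel
#'
#' Parsing is delegated to \pkg{vcfR}. Only biallelic records are retained;
#' multiallelic records are skipped with a warning giving their count. The
#' ancestral allele is taken from the `AA` INFO tag when present. The panel is
#' marked phased when every genotype separator is `|`.
#'
#' @param path VCF file (plain or gzipped).
#' @param pops optional named character vector or data.frame (`id`, `pop`)
#'   assigning population labels; unlisted samples get label `"unknown"`.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, pops = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi))
    warning(sum(multi), " multiallelic/invalid record(s) skipped")
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  aa <- suppressWarnings(vcfR::extract.info(v, element = "AA"))
  aa <- if (is.null(aa)) rep(NA_character_, length(keep)) else aa[keep]
  phased <- length(gt) > 0 && all(grepl("|", gt, fixed = TRUE) | is.na(gt))
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  tonum <- function(x) {
    y <- suppressWarnings(as.integer(x))
    y[!x %in% c("0", "1")] <- NA_integer_
    y
  }
  m1 <- matrix(tonum(a1), nrow = nrow(gt))
  m2 <- matrix(tonum(a2), nrow = nrow(gt))
  geno <- m1 + m2
  ids <- colnames(gt)
  if (is.null(pops)) {
    pop <- rep("unknown", length(ids))
  } else if (is.data.frame(pops)) {
    pop <- pops$pop[match(ids, pops$id)]
  } else pop <- unname(pops[ids])
  pop[is.na(pop)] <- "unknown"
  hap <- NULL
  if (phased) {
    hap <- matrix(0L, nrow(geno), 2L * ncol(geno))
    hap[, seq(1L, ncol(hap), 2L)] <- m1
    hap[, seq(2L, ncol(hap), 2L)] <- m2
  }
  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         aa = as.character(aa), stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  if (!is.null(hap)) hap <- hap[ord, , drop = FALSE]
  genotype_panel(variants, data.frame(id = ids, pop = pop,
                                      stringsAsFactors = FALSE), geno, hap)
}

#' Write a genotype panel to a VCF 4.2 file
#'
#' Emits phased `a|b` genotypes when the panel carries haplotypes, `a/b`
#' otherwise, and stores the ancestral allele in the `AA` INFO tag.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=backflow",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples$id), collapse = "\t"), con)
  v <- panel$variants
  info <- ifelse(is.na(v$aa), ".", paste0("AA=", v$aa))
  ns <- nrow(panel$samples)
  if (!is.null(panel$hap)) {
    h1 <- panel$hap[, seq(1L, 2L * ns, 2L), drop = FALSE]
    h2 <- panel$hap[, seq(2L, 2L * ns, 2L), drop = FALSE]
    gtm <- matrix(paste0(h1, "|", h2), nrow = nrow(v))
    gtm[is.na(h1) | is.na(h2)] <- ".|."
  } else {
    g <- panel$geno
    gtm <- matrix("./.", nrow(v), ns)
    gtm[!is.na(g) & g == 0L] <- "0/0"
    gtm[!is.na(g) & g == 1L] <- "0/1"
    gtm[!is.na(g) & g == 2L] <- "1/1"
  }
  lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                 apply(gtm, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read / write a sample-to-population label file (TSV: id, pop)
#' @param path TSV path (no header): `sample<TAB>pop`.
#' @return data.frame with columns `id`, `pop`.
#' @export
read_pop_labels <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("id", "pop"),
                         stringsAsFactors = FALSE)
  d
}

#' @rdname read_pop_labels
#' @param panel a [genotype_panel()].
#' @export
write_pop_labels <- function(panel, path) {
  utils::write.table(panel$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ----------------------------------------------------------- genetic maps --

#' Genetic map constructor
#'
#' A genetic map is a per-chromosome table of (bp, cM) anchors with
#' non-decreasing cM. Interpolation between anchors is linear; queries beyond
#' the anchored range take the boundary cM value.
#'
#' @param anchors data.frame with columns `chrom`, `pos`, `cm`.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(anchors) {
  anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "cm") %in% names(anchors)))
  sp <- split(anchors[c("pos", "cm")], anchors$chrom)
  sp <- lapply(sp, function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (is.unsorted(d$cm)) stop("cM must be non-decreasing along a chromosome")
    d
  })
  structure(list(chrom = sp), class = "genetic_map")
}

#' Uniform-rate genetic map over a simulated genome
#' @param chroms character vector of chromosome names.
#' @param length_bp chromosome length in bp (recycled).
#' @param cm_per_mb recombination rate (default 1 cM/Mb).
#' @export
uniform_map <- function(chroms, length_bp, cm_per_mb = 1) {
  length_bp <- rep_len(length_bp, length(chroms))
  genetic_map(data.frame(
    chrom = rep(chroms, each = 2L),
    pos = as.vector(rbind(1, length_bp)),
    cm = as.vector(rbind(0, length_bp / 1e6 * cm_per_mb))))
}

#' Read / write a genetic map TSV (chrom, pos_bp, cM)
#' @param path TSV file with three columns: chrom, pos, cM (no header).
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "pos", "cm"),
                         stringsAsFactors = FALSE)
  genetic_map(d)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  d <- do.call(rbind, lapply(names(map$chrom), function(ch)
    data.frame(chrom = ch, pos = map$chrom[[ch]]$pos, cm = map$chrom[[ch]]$cm)))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interpolate genetic-map position
#'
#' Linear interpolation between anchors, exact at anchors, constant beyond
#' the first/last anchor.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome name.
#' @param pos bp positions (vector).
#' @return cM positions.
#' @export
interpolate_cm <- function(map, chrom, pos) {
  d <- map$chrom[[as.character(chrom)]]
  if (is.null(d)) stop("chromosome not in map: ", chrom)
  if (nrow(d) == 1L) return(rep(d$cm, length(pos)))
  stats::approx(d$pos, d$cm, xout = pos, rule = 2, ties = "ordered")$y
}

#' Inverse map lookup: cM to bp
#' @keywords internal
interpolate_bp <- function(map, chrom, cm) {
  d <- map$chrom[[as.character(chrom)]]
  if (is.null(d)) stop("chromosome not in map: ", chrom)
  keep <- !duplicated(d$cm)
  if (sum(keep) == 1L) return(rep(d$pos[keep], length(cm)))
  stats::approx(d$cm[keep], d$pos[keep], xout = cm, rule = 2,
                ties = "ordered")$y
}

#' Attach genetic-map coordinates to a panel
#' @param panel a [genotype_panel()].
#' @param map a [genetic_map()].
#' @return The panel with `variants$cm` filled.
#' @export
attach_map <- function(panel, map) {
  for (ch in unique(panel$variants$chrom)) {
    i <- panel$variants$chrom == ch
    panel$variants$cm[i] <- interpolate_cm(map, ch, panel$variants$pos[i])
  }
  panel
}

## ------------------------------------------------------------------- QC ----

#' QC thresholds
#'
#' Defaults follow common array-QC practice: per-variant call rate >= 0.99,
#' minor allele frequency >= 0.001 and Hardy-Weinberg exact p >= 1e-6.
#'
#' @param call_rate minimum genotype success rate.
#' @param maf minimum minor allele frequency (computed on non-missing calls).
#' @param hwe_p minimum Hardy-Weinberg exact-test p-value.
#' @export
qc_config <- function(call_rate = 0.99, maf = 0.001, hwe_p = 1e-6) {
  stopifnot(call_rate >= 0, call_rate <= 1, maf >= 0, maf <= 1,
            hwe_p >= 0, hwe_p <= 1)
  structure(list(call_rate = call_rate, maf = maf, hwe_p = hwe_p),
            class = "qc_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the observed genotype counts: given the allele
#' counts, the two-sided p-value is the total probability of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count. This is the exact-test convention appropriate near the tails where
#' the chi-square approximation fails.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  hets <- seq(rare %% 2L, rare, by = 2L)
  ## log conditional probability of each heterozygote count given allele counts
  lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2L * n)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Filter variants by call rate, MAF and Hardy-Weinberg equilibrium
#'
#' A variant is kept iff it passes all three criteria. The report counts, per
#' criterion, how many variants failed it (a variant failing several criteria
#' is counted under each, but removed once).
#'
#' @param panel a [genotype_panel()].
#' @param cfg a [qc_config()].
#' @return list with elements `panel` (filtered) and `report`
#'   (data.frame: criterion, n_removed).
#' @export
qc_filter <- function(panel, cfg = qc_config()) {
  g <- panel$geno
  nv <- nrow(g)
  if (nv == 0L) {
    return(list(panel = panel,
                report = data.frame(criterion = c("call_rate", "maf", "hwe"),
                                    n_removed = c(0L, 0L, 0L))))
  }
  nonmiss <- rowSums(!is.na(g))
  call_rate <- nonmiss / ncol(g)
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(nonmiss > 0, alt / (2 * nonmiss), NA_real_)
  maf <- pmin(p, 1 - p)
  nAa <- rowSums(g == 1L, na.rm = TRUE)
  naa <- rowSums(g == 2L, na.rm = TRUE)
  nAA <- nonmiss - nAa - naa
  hwe <- vapply(seq_len(nv), function(i) {
    if (nonmiss[i] == 0) return(NA_real_)
    hwe_exact_test(nAA[i], nAa[i], naa[i])
  }, numeric(1))
  fail_cr <- call_rate < cfg$call_rate
  fail_maf <- is.na(maf) | maf < cfg$maf
  fail_hwe <- is.na(hwe) | hwe < cfg$hwe_p
  keep <- !(fail_cr | fail_maf | fail_hwe)
  list(panel = subset_panel(panel, variants = keep),
       report = data.frame(
         criterion = c("call_rate", "maf", "hwe"),
         n_removed = c(sum(fail_cr), sum(fail_maf), sum(fail_hwe))))
}

## ----------------------------------------------------------------- merge ----

#' Intersection-merge two genotype panels
#'
#' Variants are matched on (chrom, pos); a site whose ref/alt alleles are
#' swapped between the panels is harmonized by recoding dosages as `2 - d`
#' (haplotypes as `1 - h`). Strand-ambiguous A/T and C/G sites are dropped
#' with a warning. Sample ids must be disjoint.
#'
#' @param a,b [genotype_panel()] objects.
#' @return The merged `genotype_panel` on the common variants.
#' @export
merge_panels <- function(a, b) {
  if (length(intersect(a$samples$id, b$samples$id)))
    stop("duplicate sample id across panels")
  ambig <- function(v) paste(pmin(v$ref, v$alt), pmax(v$ref, v$alt)) %in%
    c("A T", "C G")
  amb_a <- ambig(a$variants); amb_b <- ambig(b$variants)
  n_amb <- sum(amb_a) + sum(amb_b)
  if (n_amb > 0) warning(n_amb, " strand-ambiguous site(s) dropped")
  a <- subset_panel(a, variants = !amb_a)
  b <- subset_panel(b, variants = !amb_b)
  key <- function(v) paste(v$chrom, v$pos)
  ia <- match(key(b$variants), key(a$variants))
  jb <- which(!is.na(ia)); ja <- ia[jb]
  same <- a$variants$ref[ja] == b$variants$ref[jb] &
    a$variants$alt[ja] == b$variants$alt[jb]
  flip <- a$variants$ref[ja] == b$variants$alt[jb] &
    a$variants$alt[ja] == b$variants$ref[jb]
  use <- same | flip
  ja <- ja[use]; jb <- jb[use]; flip <- flip[use]
  ord <- order(ja)
  ja <- ja[ord]; jb <- jb[ord]; flip <- flip[ord]
  gb <- b$geno[jb, , drop = FALSE]
  gb[flip, ] <- 2L - gb[flip, , drop = FALSE]
  hap <- NULL
  if (!is.null(a$hap) && !is.null(b$hap)) {
    hb <- b$hap[jb, , drop = FALSE]
    hb[flip, ] <- 1L - hb[flip, , drop = FALSE]
    hap <- cbind(a$hap[ja, , drop = FALSE], hb)
  }
  genotype_panel(a$variants[ja, , drop = FALSE],
                 rbind(a$samples, b$samples),
                 cbind(a$geno[ja, , drop = FALSE], gb), hap)
}
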