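## Synthetic-data generator: forward-time Wright-Fisher demography with
## tracked ancestry tracts, a fast frequency-level drift simulator, and a
## Y-lineage Poisson mutation simulator. Ground truth (admixture fractions,
## pulse times, tracts) is recorded for recovery tests.

#' Demographic event constructors
#'
#' Events are interpreted in forward time: generation 0 is the root epoch and
#' generations increase toward the present (the sampling events).
#'
#' @param parent,child,pop,recipient,donor population names.
#' @param gen,gen_start,gen_end forward generation indices.
#' @param size diploid population size during a bottleneck.
#' @param alpha admixture proportion in `[0, 1)`; `alpha = 0` is an explicit
#'   no-flow pulse.
#' @param n number of diploids to sample.
#' @return A list describing the event.
#' @export
ev_split <- function(parent, child, gen) {
  list(type = "split", parent = parent, child = child, gen = gen)
}

#' @rdname ev_split
#' @export
ev_bottleneck <- function(pop, gen_start, gen_end, size) {
  stopifnot(gen_end > gen_start, size >= 1)
  list(type = "bottleneck", pop = pop, gen_start = gen_start,
       gen_end = gen_end, size = size)
}

#' @rdname ev_split
#' @export
ev_pulse <- function(recipient, donor, alpha, gen) {
  list(type = "pulse", recipient = recipient, donor = donor,
       alpha = alpha, gen = gen)
}

#' @rdname ev_split
#' @export
ev_sampling <- function(pop, n, gen) {
  list(type = "sampling", pop = pop, n = n, gen = gen)
}

#' Genome layout for the simulators
#'
#' The forward simulator works on a fixed grid of segregating sites
#' (infinite-sites on a finite grid): standing variation is seeded at the
#' root and recombined/drifted forward; no de-novo mutation influx is applied
#' during the simulated epochs, which is negligible over the time depths the
#' package simulates.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_bp chromosome length in bp.
#' @param n_snps total number of segregating sites (spread over chromosomes).
#' @param mu per-site per-generation mutation rate (carried for
#'   documentation/conversion; default 1.25e-8).
#' @param cm_per_mb uniform recombination rate; ignored when `map` is given.
#' @param map optional [genetic_map()] replacing the uniform map.
#' @export
genome_config <- function(n_chrom = 10, chrom_bp = 2e7, n_snps = 2e4,
                          mu = 1.25e-8, cm_per_mb = 1, map = NULL) {
  stopifnot(n_chrom >= 1, chrom_bp > 0, n_snps >= 1, mu >= 0, cm_per_mb >= 0)
  structure(list(n_chrom = n_chrom, chrom_bp = chrom_bp, n_snps = n_snps,
                 mu = mu, cm_per_mb = cm_per_mb, map = map),
            class = "genome_config")
}

#' Demography configuration
#'
#' @param populations named numeric vector of diploid population sizes.
#' @param events list of events built with [ev_split()], [ev_bottleneck()],
#'   [ev_pulse()], [ev_sampling()].
#' @param genome a [genome_config()].
#' @param generation_time years per generation (default 30).
#' @param seed integer seed; the same seed yields byte-identical output.
#' @param outgroup if `TRUE`, simulated panels include an artificial `Chimp`
#'   outgroup fixed for the ancestral allele at every site (needed by the
#'   f4/D outgroup slot).
#' @return An object of class `demography_config`.
#' @export
demography_config <- function(populations, events, genome = genome_config(),
                              generation_time = 30, seed = 1L,
                              outgroup = TRUE) {
  if (is.null(names(populations)) || any(!nzchar(names(populations))))
    stop("populations must be a named vector of diploid sizes")
  if (any(populations < 1)) stop("population sizes must be >= 1")
  cfg <- structure(list(populations = populations, events = events,
                        genome = genome, generation_time = generation_time,
                        seed = as.integer(seed), outgroup = outgroup),
                   class = "demography_config")
  validate_demography(cfg)
  cfg
}

validate_demography <- function(cfg) {
  pops <- names(cfg$populations)
  ev <- cfg$events
  types <- vapply(ev, `[[`, "", "type")
  for (e in ev) {
    nm <- setdiff(unlist(e[names(e) %in%
                            c("pop", "parent", "child", "recipient", "donor")]),
                  pops)
    if (length(nm))
      stop("configuration error in ", e$type, " event: unknown population ",
           paste(nm, collapse = ", "))
  }
  for (e in ev[types == "pulse"]) {
    if (e$alpha < 0 || e$alpha >= 1)
      stop("configuration error in pulse event (", e$donor, " -> ",
           e$recipient, "): alpha must be in [0, 1)")
  }
  ## birth generation of each population
  birth <- stats::setNames(rep(0, length(pops)), pops)
  for (e in ev[types == "split"]) birth[e$child] <- e$gen
  samp_gen <- stats::setNames(rep(Inf, length(pops)), pops)
  for (e in ev[types == "sampling"]) samp_gen[e$pop] <- min(samp_gen[e$pop], e$gen)
  for (e in ev) {
    gens <- switch(e$type,
                   split = c(parent = e$gen, child = e$gen),
                   bottleneck = stats::setNames(e$gen_start, e$pop),
                   pulse = c(e$gen, e$gen),
                   sampling = stats::setNames(e$gen, e$pop))
    refs <- switch(e$type,
                   split = c(e$parent, e$child),
                   bottleneck = e$pop,
                   pulse = c(e$recipient, e$donor),
                   sampling = e$pop)
    for (k in seq_along(refs)) {
      p <- refs[k]
      if (gens[k] < birth[p])
        stop("configuration error in ", e$type,
             " event: population ", p, " does not exist yet at generation ",
             gens[k])
      if (e$type != "sampling" && gens[k] > samp_gen[p])
        stop("configuration error: ", e$type, " event at generation ",
             gens[k], " occurs after sampling of population ", p)
    }
  }
  invisible(cfg)
}

## diploid size of pop at a given forward generation, honoring bottlenecks
size_at <- function(cfg, pop, gen) {
  sz <- cfg$populations[[pop]]
  for (e in cfg$events) {
    if (e$type == "bottleneck" && e$pop == pop &&
        gen >= e$gen_start && gen < e$gen_end)
      sz <- e$size
  }
  sz
}

sorted_events <- function(cfg) {
  ev <- cfg$events
  types <- vapply(ev, `[[`, "", "type")
  prio <- c(split = 1, bottleneck = 2, pulse = 3, sampling = 4)
  gen <- vapply(ev, function(e)
    if (e$type == "bottleneck") e$gen_start else e$gen, numeric(1))
  ev[order(gen, prio[types], seq_along(ev))]
}

## Drift a frequency vector forward `from` -> `to` generations by binomial
## Wright-Fisher sampling of 2N gametes per generation.
drift_forward <- function(cfg, pop, p, from, to) {
  if (to <= from) return(p)
  for (g in seq(from + 1, to)) {
    n2 <- 2L * as.integer(size_at(cfg, pop, g))
    p <- stats::rbinom(length(p), n2, p) / n2
  }
  p
}

## Event-driven frequency engine shared by simulate_freqs and simulate_panel.
## Returns realized population frequencies at every sampling event and, when
## capture = TRUE, the frequency vectors needed to found haplotype
## populations (recipient at first pulse, donor at each pulse).
run_freq_engine <- function(cfg, n_snps, ancestral = c(0.05, 0.95),
                            capture = FALSE) {
  p0 <- stats::runif(n_snps, ancestral[1], ancestral[2])
  pops <- names(cfg$populations)
  types <- vapply(cfg$events, `[[`, "", "type")
  children <- vapply(cfg$events[types == "split"], `[[`, "", "child")
  state <- new.env(parent = emptyenv())
  state$p <- list(); state$gen <- list()
  for (pp in setdiff(pops, children)) {    # root populations at generation 0
    state$p[[pp]] <- p0
    state$gen[[pp]] <- 0
  }
  adv <- function(pop, to) {
    if (is.null(state$p[[pop]]))
      stop("population ", pop, " not alive")
    state$p[[pop]] <- drift_forward(cfg, pop, state$p[[pop]],
                                    state$gen[[pop]], to)
    state$gen[[pop]] <- to
  }
  samples <- list(); pulses <- list(); founders <- list()
  for (e in sorted_events(cfg)) {
    switch(e$type,
           split = {
             adv(e$parent, e$gen)
             state$p[[e$child]] <- state$p[[e$parent]]
             state$gen[[e$child]] <- e$gen
           },
           bottleneck = NULL,              # handled by size_at during drift
           pulse = {
             adv(e$recipient, e$gen); adv(e$donor, e$gen)
             rec <- list(recipient = e$recipient, donor = e$donor,
                         alpha = e$alpha, gen = e$gen)
             if (capture) {
               rec$p_recipient <- state$p[[e$recipient]]
               rec$p_donor <- state$p[[e$donor]]
             }
             pulses[[length(pulses) + 1L]] <- rec
             state$p[[e$recipient]] <- e$alpha * state$p[[e$donor]] +
               (1 - e$alpha) * state$p[[e$recipient]]
           },
           sampling = {
             adv(e$pop, e$gen)
             samples[[length(samples) + 1L]] <-
               list(pop = e$pop, n = e$n, gen = e$gen, p = state$p[[e$pop]])
           })
  }
  list(p0 = p0, samples = samples, pulses = pulses)
}

#' Frequency-level Wright-Fisher simulation
#'
#' Applies binomial drift directly to derived-allele frequencies along the
#' population tree, mixing frequencies as `alpha * p_donor +
#' (1 - alpha) * p_recipient` at admixture pulses. A fast oracle for
#' f-statistics: no haplotypes or linkage are involved.
#'
#' @param config a [demography_config()].
#' @param n_snps number of independent SNPs.
#' @param ancestral range of the uniform ancestral-frequency draw
#'   (default `c(0.05, 0.95)`).
#' @return A list of class `freq_sim`: `freqs` (a [freq_table()] of sampled
#'   allele-frequency estimates, including the `Chimp` outgroup column when
#'   configured), `true_p` (matrix of realized population frequencies at
#'   sampling), and `truth` (ancestral frequencies and pulse table).
#' @export
simulate_freqs <- function(config, n_snps, ancestral = c(0.05, 0.95)) {
  stopifnot(n_snps >= 1)
  set.seed(config$seed)
  eng <- run_freq_engine(config, n_snps, ancestral)
  pops <- vapply(eng$samples, `[[`, "", "pop")
  true_p <- vapply(eng$samples, `[[`, numeric(n_snps), "p")
  if (n_snps == 1L) true_p <- matrix(true_p, nrow = 1L)
  colnames(true_p) <- pops
  nmat <- matrix(rep(2L * vapply(eng$samples, function(s) as.integer(s$n),
                                 1L), each = n_snps),
                 nrow = n_snps, dimnames = list(NULL, pops))
  phat <- true_p
  for (j in seq_along(pops))
    phat[, j] <- stats::rbinom(n_snps, nmat[1, j], true_p[, j]) / nmat[1, j]
  if (isTRUE(config$outgroup)) {
    phat <- cbind(phat, Chimp = 0)
    nmat <- cbind(nmat, Chimp = nmat[, 1])
    true_p <- cbind(true_p, Chimp = 0)
  }
  pulses <- if (length(eng$pulses))
    do.call(rbind, lapply(eng$pulses, function(pl)
      data.frame(recipient = pl$recipient, donor = pl$donor,
                 alpha = pl$alpha, gen = pl$gen)))
  else data.frame(recipient = character(), donor = character(),
                  alpha = numeric(), gen = numeric())
  structure(list(freqs = freq_table(phat, nmat),
                 true_p = true_p,
                 truth = list(ancestral = eng$p0, pulses = pulses)),
            class = "freq_sim")
}

## ------------------------------------------------- haplotype forward sim ----

## Crossover phase of one gamete along one chromosome. Returns logical: TRUE
## where the gamete copies the first parental haplotype. Crossover count is
## Poisson(map length in Morgans), positions uniform in cM (no interference).
gamete_phase <- function(snp_cm, cm_len, n_cx, start_first) {
  if (n_cx == 0L)
    return(rep(start_first, length(snp_cm)))
  brk <- sort(stats::runif(n_cx, 0, cm_len))
  idx <- findInterval(snp_cm, brk)
  ((idx %% 2L) == 0L) == start_first
}

## Forward random-mating propagation of founder-haplotype indices for one
## recipient population on one chromosome. `pedigree` is a list per
## generation with $parent (individual index per gamete), $mig_idx and
## $mig_fid (gametes replaced by fresh donor founders at later pulses).
propagate_chrom <- function(slot_fid, pedigree, snp_cm, cm_len) {
  n_c <- length(snp_cm)
  cur <- matrix(rep(slot_fid, each = n_c), nrow = n_c)
  for (ped in pedigree) {
    np <- length(ped$parent)
    n_cx <- stats::rpois(np, cm_len / 100)
    first <- stats::runif(np) < 0.5
    start_col <- 2L * ped$parent - as.integer(first)
    new <- cur[, start_col, drop = FALSE]        # no-crossover fast path
    for (j in which(n_cx > 0L)) {
      ph <- gamete_phase(snp_cm, cm_len, n_cx[j], first[j])
      other <- 2L * ped$parent[j] - as.integer(!first[j])
      new[!ph, j] <- cur[!ph, other]
    }
    if (length(ped$mig_idx))
      new[, ped$mig_idx] <- rep(ped$mig_fid, each = n_c)
    cur <- new
  }
  cur
}

#' Forward-time Wright-Fisher simulation of a genotype panel
#'
#' Population allele frequencies are drifted along the demographic tree at
#' the frequency level; for each admixture-pulse recipient, a diploid
#' population is instantiated at its first pulse and mated forward with
#' Poisson recombination, tracking for every haplotype which founder (donor
#' or resident) each segment descends from. Pulses copy whole donor
#' haplotypes with probability `alpha` per gamete. Sampled haplotypes are
#' materialized by drawing founder alleles from the corresponding population
#' frequencies; unadmixed populations are drawn site-wise at sampling.
#'
#' @param config a [demography_config()].
#' @return A list of class `panel_sim`: `panel` (phased [genotype_panel()]
#'   with ancestral alleles and population labels), `truth` (a
#'   `truth_record`: ancestry tracts in 0-based half-open bp coordinates,
#'   pulse table, realized frequencies) and `map` (the [genetic_map()] used).
#' @export
simulate_panel <- function(config) {
  set.seed(config$seed)
  gnm <- config$genome
  chroms <- paste0("chr", seq_len(gnm$n_chrom))
  map <- if (is.null(gnm$map))
    uniform_map(chroms, gnm$chrom_bp, gnm$cm_per_mb) else gnm$map
  ## variant grid
  n_per <- diff(round(seq(0, gnm$n_snps, length.out = gnm$n_chrom + 1)))
  vlist <- lapply(seq_len(gnm$n_chrom), function(ci) {
    pos <- sort(sample.int(gnm$chrom_bp - 2L, n_per[ci]) + 1L)
    data.frame(chrom = chroms[ci], pos = pos, stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, vlist)
  variants$ref <- "A"; variants$alt <- "G"; variants$aa <- "A"
  variants$cm <- NA_real_
  chrom_of <- variants$chrom
  n_snps <- nrow(variants)
  snp_cm <- lapply(chroms, function(ch)
    interpolate_cm(map, ch, variants$pos[chrom_of == ch]))
  names(snp_cm) <- chroms
  cm_len <- vapply(chroms, function(ch) {
    d <- map$chrom[[ch]]; max(d$cm) - min(d$cm)
  }, numeric(1))

  eng <- run_freq_engine(config, n_snps, capture = TRUE)
  pulse_df <- if (length(eng$pulses))
    do.call(rbind, lapply(eng$pulses, function(pl)
      data.frame(recipient = pl$recipient, donor = pl$donor,
                 alpha = pl$alpha, gen = pl$gen)))
  else data.frame(recipient = character(), donor = character(),
                  alpha = numeric(), gen = numeric())
  recipients <- unique(pulse_df$recipient[pulse_df$alpha > 0])

  hap_blocks <- list(); anc_blocks <- list(); sample_df <- list()
  for (s in eng$samples) {
    n_hap <- 2L * s$n
    ids <- sprintf("%s_%d", s$pop, seq_len(s$n))
    sample_df[[length(sample_df) + 1L]] <-
      data.frame(id = ids, pop = s$pop, stringsAsFactors = FALSE)
    if (!(s$pop %in% recipients)) {
      hap <- matrix(stats::rbinom(n_snps * n_hap, 1L, rep(s$p, n_hap)),
                    nrow = n_snps)
      anc <- matrix(s$pop, n_snps, n_hap)
    } else {
      res <- sim_recipient_haps(config, s, eng$pulses, snp_cm, cm_len,
                                chrom_of, chroms)
      hap <- res$hap; anc <- res$anc
    }
    hap_blocks[[length(hap_blocks) + 1L]] <- hap
    anc_blocks[[length(anc_blocks) + 1L]] <- anc
  }
  if (isTRUE(config$outgroup)) {
    sample_df[[length(sample_df) + 1L]] <-
      data.frame(id = "Chimp_1", pop = "Chimp", stringsAsFactors = FALSE)
    hap_blocks[[length(hap_blocks) + 1L]] <- matrix(0L, n_snps, 2L)
    anc_blocks[[length(anc_blocks) + 1L]] <- matrix("Chimp", n_snps, 2L)
  }
  samples <- do.call(rbind, sample_df)
  hap <- do.call(cbind, hap_blocks)
  anc <- do.call(cbind, anc_blocks)
  geno <- hap[, seq(1L, ncol(hap), 2L), drop = FALSE] +
    hap[, seq(2L, ncol(hap), 2L), drop = FALSE]
  panel <- genotype_panel(variants, samples, geno, hap)
  panel <- attach_map(panel, map)
  tracts <- ancestry_tracts(anc, samples, chrom_of, variants$pos,
                            gnm$chrom_bp, chroms)
  true_p <- vapply(eng$samples, `[[`, numeric(n_snps), "p")
  if (n_snps == 1L) true_p <- matrix(true_p, nrow = 1L)
  colnames(true_p) <- vapply(eng$samples, `[[`, "", "pop")
  truth <- structure(list(tracts = tracts, pulses = pulse_df,
                          freqs = true_p, ancestral = eng$p0),
                     class = "truth_record")
  structure(list(panel = panel, truth = truth, map = map),
            class = "panel_sim")
}

## Haplotype-stage simulation for one admixture-pulse recipient population.
sim_recipient_haps <- function(config, s, pulses, snp_cm, cm_len,
                               chrom_of, chroms) {
  pl <- Filter(function(p) p$recipient == s$pop && p$alpha > 0, pulses)
  pl <- pl[order(vapply(pl, `[[`, numeric(1), "gen"))]
  g1 <- pl[[1]]$gen
  n_snps <- length(chrom_of)
  N1 <- as.integer(size_at(config, s$pop, g1))
  ## founder sources: frequency vector each founder's alleles are drawn from
  src_freq <- list(pl[[1]]$p_recipient, pl[[1]]$p_donor)
  src_label <- c(s$pop, pl[[1]]$donor)
  is_donor <- stats::runif(2L * N1) < pl[[1]]$alpha
  slot_src <- ifelse(is_donor, 2L, 1L)
  founder_src <- slot_src                      # per-founder source index
  slot_fid <- seq_len(2L * N1)                 # founder id occupying slot
  ## pedigree from g1+1 to sampling generation, with later pulses
  later <- pl[-1]
  later_gen <- vapply(later, `[[`, numeric(1), "gen")
  pedigree <- list()
  N_prev <- N1
  gens <- if (s$gen > g1) seq(g1 + 1, s$gen) else numeric(0)
  for (g in gens) {
    N_g <- as.integer(size_at(config, s$pop, g))
    ped <- list(parent = sample.int(N_prev, 2L * N_g, replace = TRUE),
                mig_idx = integer(0), mig_fid = integer(0))
    hit <- which(later_gen == g)
    for (k in hit) {
      mig <- which(stats::runif(2L * N_g) < later[[k]]$alpha)
      if (length(mig)) {
        src_freq[[length(src_freq) + 1L]] <- later[[k]]$p_donor
        src_label <- c(src_label, later[[k]]$donor)
        fid <- length(founder_src) + seq_along(mig)
        founder_src <- c(founder_src,
                         rep(length(src_freq), length(mig)))
        ped$mig_idx <- c(ped$mig_idx, mig)
        ped$mig_fid <- c(ped$mig_fid, fid)
      }
    }
    pedigree[[length(pedigree) + 1L]] <- ped
    N_prev <- N_g
  }
  pick <- sample.int(N_prev, s$n)
  cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  hap <- matrix(0L, n_snps, 2L * s$n)
  ancs <- matrix("", n_snps, 2L * s$n)
  for (ch in chroms) {
    rows <- which(chrom_of == ch)
    fin <- propagate_chrom(slot_fid, pedigree, snp_cm[[ch]], cm_len[[ch]])
    fin <- fin[, cols, drop = FALSE]
    used <- sort(unique(as.vector(fin)))
    ## founder allele draws restricted to founders actually inherited
    al <- matrix(0L, length(rows), length(used))
    for (u in seq_along(used)) {
      p <- src_freq[[founder_src[used[u]]]][rows]
      al[, u] <- stats::rbinom(length(rows), 1L, p)
    }
    idx <- matrix(match(fin, used), nrow = length(rows))
    hap[rows, ] <- al[cbind(rep(seq_along(rows), ncol(fin)),
                            as.vector(idx))]
    ancs[rows, ] <- src_label[founder_src[fin]]
  }
  list(hap = hap, anc = ancs)
}

## Convert per-SNP ancestry labels of sampled haplotypes into bp tracts that
## tile each chromosome (0-based half-open; boundaries at midpoints between
## adjacent SNPs of differing ancestry).
ancestry_tracts <- function(anc, samples, chrom_of, pos, chrom_bp, chroms) {
  out <- vector("list", 2L * nrow(samples) * length(chroms))
  k <- 0L
  for (ci in seq_along(chroms)) {
    rows <- which(chrom_of == chroms[ci])
    p <- pos[rows]
    mid <- if (length(p) > 1) floor((p[-1] + p[-length(p)]) / 2) else integer(0)
    for (h in seq_len(ncol(anc))) {
      si <- (h + 1L) %/% 2L
      r <- rle(anc[rows, h])
      ends_i <- cumsum(r$lengths)
      starts <- c(0, mid[ends_i[-length(ends_i)]])
      ends <- c(mid[ends_i[-length(ends_i)]], chrom_bp)
      k <- k + 1L
      out[[k]] <- data.frame(sample = samples$id[si],
                             haplotype = 2L - (h %% 2L),
                             chrom = chroms[ci],
                             start = starts, end = ends,
                             ancestry = r$values,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Tract-length-weighted ancestry fractions from a truth record
#'
#' @param truth the `truth` element of a [simulate_panel()] result.
#' @param samples optional sample ids to restrict to.
#' @return Named numeric vector of genome fractions per ancestry label.
#' @export
ancestry_fraction <- function(truth, samples = NULL) {
  tr <- truth$tracts
  if (!is.null(samples)) tr <- tr[tr$sample %in% samples, , drop = FALSE]
  len <- tapply(tr$end - tr$start, tr$ancestry, sum)
  len / sum(len)
}

#' Write a simulated panel to disk
#'
#' Emits the VCF (phased GT, AA INFO tag), the population TSV, the genetic
#' map TSV and the truth tracts as a BED-like TSV (0-based half-open).
#'
#' @param sim a `panel_sim` from [simulate_panel()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the files written.
#' @export
simulate_to_files <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
         pops = file.path(dir, paste0(prefix, ".pops.tsv")),
         map = file.path(dir, paste0(prefix, ".map.tsv")),
         tracts = file.path(dir, paste0(prefix, ".tracts.tsv")))
  write_vcf(sim$panel, f["vcf"])
  write_pop_labels(sim$panel, f["pops"])
  write_genetic_map(sim$map, f["map"])
  utils::write.table(sim$truth$tracts, f["tracts"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  f
}

## ------------------------------------------------------- canned scenarios ----

#' Named demographic presets
#'
#' These presets are this package's own desk-scale renderings of a deep
#' African/Eurasian history: `"ooa_bottleneck"` is an African/Eurasian split
#' (forward generation 200 of 1200; 30-yr generations place it roughly 30 kya
#' before sampling) with a strong bottleneck on the Eurasian branch, leaving
#' Eurasian heterozygosity at roughly 0.8 of the African level.
#' `"chad_double_pulse"` adds a recipient population that splits from the
#' African branch and receives an older small Eurasian pulse (alpha = 0.1,
#' 150 generations before sampling) and a younger larger one (alpha = 0.2,
#' 10 generations before sampling).
#'
#' @param name preset name; `NULL` lists available names.
#' @param genome optional [genome_config()] overriding the preset's genome
#'   (handy for scaling simulations up or down).
#' @param seed optional seed override.
#' @return A [demography_config()], or the preset names when `name` is NULL.
#' @export
canned_scenarios <- function(name = NULL, genome = NULL, seed = NULL) {
  presets <- list(
    ooa_bottleneck = function() demography_config(
      populations = c(African = 5000, Eurasian = 2500),
      events = list(
        ev_split("African", "Eurasian", 950),
        ev_bottleneck("Eurasian", 950, 1200, 400),
        ev_sampling("African", 25, 1200),
        ev_sampling("Eurasian", 25, 1200)),
      genome = genome_config(n_chrom = 5, chrom_bp = 2e7, n_snps = 5000),
      seed = 1806L),
    chad_double_pulse = function() demography_config(
      populations = c(African = 5000, Eurasian = 2500, Recipient = 4000),
      events = list(
        ev_split("African", "Eurasian", 950),
        ev_bottleneck("Eurasian", 950, 1200, 400),
        ev_split("African", "Recipient", 1040),
        ev_pulse("Recipient", "Eurasian", 0.10, 1050),
        ev_pulse("Recipient", "Eurasian", 0.20, 1190),
        ev_sampling("Recipient", 50, 1200),
        ev_sampling("African", 40, 1200),
        ev_sampling("Eurasian", 40, 1200)),
      genome = genome_config(n_chrom = 10, chrom_bp = 2e7, n_snps = 10000),
      seed = 2453L))
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets))
    stop("unknown scenario: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  cfg <- presets[[name]]()
  if (!is.null(genome)) cfg$genome <- genome
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

## -------------------------------------------------------- Y-lineage sim ----

#' Star tree helper for the Y simulator
#' @param n_tips number of haplotypes.
#' @param age_years age of the single internal node.
#' @return An \pkg{ape} `phylo` object with branch lengths in years.
#' @export
y_star_tree <- function(n_tips, age_years) {
  tr <- ape::stree(n_tips, type = "star")
  tr$edge.length <- rep(age_years, nrow(tr$edge))
  tr
}

#' Configuration for the Y-lineage mutation simulator
#'
#' @param tree rooted \pkg{ape} `phylo` with branch lengths in years
#'   (assumed ultrametric for age reporting).
#' @param mu per-site per-year mutation rate (default 0.76e-9).
#' @param L number of callable sites.
#' @param seed integer seed.
#' @export
y_sim_config <- function(tree, mu = 0.76e-9, L = 1e7, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            all(tree$edge.length >= 0), mu >= 0, L > 0)
  structure(list(tree = tree, mu = mu, L = L, seed = as.integer(seed)),
            class = "y_sim_config")
}

## tip labels below each edge of a phylo tree (postorder accumulation)
edge_tipsets <- function(tree) {
  n_tip <- length(tree$tip.label)
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- i
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e)
    tree$tip.label[sort(below[[tree$edge[e, 2]]])])
}

#' Simulate Y-chromosome derived-allele matrices on a known tree
#'
#' Mutations accumulate on each branch as Poisson(mu * L * branch years)
#' under infinite sites, so the resulting tips x sites matrix is consistent
#' with a perfect phylogeny by construction. A warning is issued when the
#' expected fraction of recurrently hit sites exceeds 1%.
#'
#' @param config a [y_sim_config()].
#' @return list of class `y_sim`: `matrix` (tips x mutations, 0/1),
#'   `node_ages` (true ages in years, named by node number), `tree`.
#' @export
simulate_y <- function(config) {
  set.seed(config$seed)
  tree <- config$tree
  M <- config$mu * config$L * sum(tree$edge.length)
  if (M > 1 && (M - 1) / (2 * config$L) > 0.01)
    warning("expected recurrent-mutation fraction exceeds 1%; ",
            "infinite-sites approximation is strained")
  tipsets <- edge_tipsets(tree)
  counts <- stats::rpois(nrow(tree$edge),
                         config$mu * config$L * tree$edge.length)
  n_tip <- length(tree$tip.label)
  total <- sum(counts)
  mat <- matrix(0L, n_tip, total,
                dimnames = list(tree$tip.label,
                                if (total) paste0("m", seq_len(total))))
  col <- 0L
  for (e in seq_along(counts)) {
    if (counts[e] == 0L) next
    rows <- match(tipsets[[e]], tree$tip.label)
    mat[rows, col + seq_len(counts[e])] <- 1L
    col <- col + counts[e]
  }
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth[seq_len(n_tip)]) - depth
  names(ages) <- seq_along(ages)
  structure(list(matrix = mat,
                 node_ages = ages[-seq_len(n_tip)],
                 tree = tree, branch_mutations = counts),
            class = "y_sim")
}
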