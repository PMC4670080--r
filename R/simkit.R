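#' Forward pedigree simulation of an admixed cohort
#'
#' Simulates a population forward in time under a pulse-migration schedule and
#' returns true ancestry tracts for the sampled generation. The founding
#' generation consists entirely of migrants drawn from the founding fractions;
#' at each later generation every individual is, with probability equal to the
#' generation's total replacement fraction, a new migrant (source drawn
#' proportionally to the per-source fractions), and otherwise the child of a
#' randomly mated monogamous pair of the previous generation. Transmitted
#' chromosomes are meiotic recombinants with Poisson(length in Morgans)
#' crossovers at uniform positions, a fair-coin starting haplotype and no
#' interference.
#'
#' The pedigree population size defaults to \code{max(200, 10 * nIndividuals)}.
#' This limits, but at deep founding times does not eliminate, pedigree
#' collapse: lineages of one chromosome can revisit shared ancestors, which
#' makes simulated tract spectra deviate slightly from the infinite-population
#' analytic model. Increase \code{pedigreeSize} when using the simulator as a
#' numerical oracle for [expectedTractSpectrum()].
#'
#' @param schedule A [MigrationSchedule-class].
#' @param chroms A [ChromosomeSet-class].
#' @param nIndividuals Number of diploid individuals to sample (generation 1).
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param pedigreeSize Population size per ancestral generation.
#' @return A [SimulatedCohort-class] with true tracts (posterior 1).
#' @examples
#' sched <- buildMigrationSchedule("BASE", c(12, 6), c(EUR = .65, NAT = .30, AFR = .05))
#' coh <- simulateCohort(sched, chromosomeSet(c(chr1 = 100)), 5, seed = 1)
#' head(tracts(coh))
#' @export
simulateCohort <- function(schedule, chroms, nIndividuals, seed,
                           pedigreeSize = max(200L, 10L * nIndividuals)) {
  stopifnot(is(schedule, "MigrationSchedule"), is(chroms, "ChromosomeSet"))
  if (nIndividuals < 1) stop("nIndividuals must be >= 1")
  validObject(schedule); validObject(chroms)
  set.seed(as.integer(seed))
  raw <- simulate_pedigree_cpp(migrationMatrix(schedule), chromLengths(chroms),
                               as.integer(nIndividuals), as.integer(pedigreeSize))
  tr <- data.frame(hap = raw$hap,
                   chrom = chromNames(chroms)[raw$chrom],
                   start = raw$start, end = raw$end,
                   ancestry = populations(schedule)[raw$anc],
                   posterior = 1.0,
                   stringsAsFactors = FALSE)
  new("SimulatedCohort", tracts = tr, chroms = chroms, alleles = NULL,
      loci = NULL, schedule = schedule, seed = as.integer(seed),
      plantedIBD = data.frame(hapA = integer(), hapB = integer(),
                              chrom = character(), start = numeric(),
                              end = numeric()))
}

#' Draw ancestry-specific allele frequencies (Balding-Nichols model)
#'
#' Per-locus ancestral frequencies are Uniform(0.05, 0.95); each source
#' population's frequency is Beta(p (1-F)/F, (1-p)(1-F)/F) around the
#' ancestral value, where F is the drift (FST-like) parameter. Loci are placed
#' uniformly on the genetic map.
#'
#' @param nLoci Number of loci.
#' @param nPops Number of source populations.
#' @param fst Drift parameter, strictly between 0 and 1.
#' @param chroms A [ChromosomeSet-class].
#' @param seed Integer seed.
#' @param populations Optional population labels (default pop1..popK).
#' @return An [AncestralFrequencies-class]; loci sorted by chromosome, position.
#' @export
drawAncestralFrequencies <- function(nLoci, nPops, fst, chroms, seed,
                                     populations = paste0("pop", seq_len(nPops))) {
  if (!(fst > 0 && fst < 1)) stop("fst must lie strictly in (0, 1)")
  stopifnot(is(chroms, "ChromosomeSet"))
  set.seed(as.integer(seed))
  if (nLoci == 0) {
    return(new("AncestralFrequencies",
               freq = matrix(numeric(), 0, nPops, dimnames = list(NULL, populations)),
               chrom = character(), cM = numeric(), fst = fst))
  }
  L <- chromLengths(chroms)
  u <- runif(nLoci, 0, sum(L))
  cum <- cumsum(L)
  ci <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
  pos <- u - c(0, cum)[ci]
  o <- order(ci, pos)
  ci <- ci[o]; pos <- pos[o]
  p0 <- runif(nLoci, 0.05, 0.95)
  shape <- (1 - fst) / fst
  fr <- matrix(rbeta(nLoci * nPops, rep(p0, nPops) * shape,
                     rep(1 - p0, nPops) * shape),
               nrow = nLoci, ncol = nPops,
               dimnames = list(NULL, populations))
  fr[fr < 1e-6] <- 1e-6
  fr[fr > 1 - 1e-6] <- 1 - 1e-6
  new("AncestralFrequencies", freq = fr, chrom = chromNames(chroms)[ci],
      cM = pos, fst = fst)
}

#' Paint simulated haplotypes with alleles
#'
#' Draws a 0/1 allele at every locus of every haplotype: Bernoulli with the
#' locus frequency in the source population of the overlapping ancestry tract.
#'
#' @param cohort A [SimulatedCohort-class].
#' @param freqs An [AncestralFrequencies-class] whose populations cover the
#'   cohort's ancestries and whose loci fall on the cohort's chromosomes.
#' @param seed Integer seed.
#' @return The cohort with \code{alleles} (haplotypes x loci) and \code{loci}
#'   filled in.
#' @export
paintHaplotypes <- function(cohort, freqs, seed) {
  stopifnot(is(cohort, "SimulatedCohort"), is(freqs, "AncestralFrequencies"))
  tr <- cohort@tracts
  anc <- unique(tr$ancestry)
  if (!all(anc %in% colnames(freqs@freq)))
    stop("frequencies missing ancestries: ",
         paste(setdiff(anc, colnames(freqs@freq)), collapse = ", "))
  if (!all(unique(freqs@chrom) %in% chromNames(cohort@chroms)))
    stop("frequency loci on chromosomes absent from the cohort")
  set.seed(as.integer(seed))
  nhap <- 2L * nIndividuals(cohort)
  nloc <- length(freqs@cM)
  al <- matrix(NA_integer_, nhap, nloc,
               dimnames = list(paste0("hap", seq_len(nhap)), NULL))
  key <- paste0(tr$chrom, "|", tr$hap)
  trs <- split(seq_len(nrow(tr)), key)
  for (ch in unique(freqs@chrom)) {
    sel <- which(freqs@chrom == ch)
    pos <- freqs@cM[sel]
    for (h in seq_len(nhap)) {
      idx <- trs[[paste0(ch, "|", h)]]
      if (is.null(idx)) stop("haplotype ", h, " has no tracts on ", ch)
      idx <- idx[order(tr$start[idx])]
      ti <- findInterval(pos, tr$start[idx], rightmost.closed = FALSE)
      if (any(ti == 0) || any(pos >= tr$end[idx][ti] + 1e-9))
        stop("locus outside any tract on ", ch, " hap ", h,
             " (tracts must tile the chromosome)")
      p <- freqs@freq[cbind(sel, match(tr$ancestry[idx][ti], colnames(freqs@freq)))]
      al[h, sel] <- rbinom(length(sel), 1L, p)
    }
  }
  cohort@alleles <- al
  cohort@loci <- data.frame(chrom = freqs@chrom, cM = freqs@cM,
                            stringsAsFactors = FALSE)
  cohort
}

#' Plant an IBD segment between two haplotypes
#'
#' Overwrites the alleles of \code{hapB} on \code{[startCM, endCM)} with those
#' of \code{hapA} and records the interval as ground truth for testing IBD
#' detection. Overlapping plants on the same haplotype pair are rejected so
#' the recorded truth stays unambiguous.
#'
#' @param cohort A painted [SimulatedCohort-class].
#' @param hapA,hapB Haplotype indices (1-based).
#' @param chrom Chromosome name.
#' @param startCM,endCM Interval in cM, half-open, within the chromosome.
#' @return The modified cohort.
#' @export
plantIBDSegment <- function(cohort, hapA, hapB, chrom, startCM, endCM) {
  stopifnot(is(cohort, "SimulatedCohort"))
  if (is.null(cohort@alleles)) stop("paint haplotypes before planting IBD segments")
  if (!(chrom %in% chromNames(cohort@chroms))) stop("unknown chromosome ", chrom)
  L <- chromLengths(cohort@chroms)[chrom]
  if (!(endCM > startCM)) stop("end must be greater than start")
  if (startCM < 0 || endCM > L + 1e-9) stop("interval outside chromosome")
  pl <- cohort@plantedIBD
  samepair <- (pl$hapA == hapA & pl$hapB == hapB) |
              (pl$hapA == hapB & pl$hapB == hapA)
  if (any(samepair & pl$chrom == chrom & pl$start < endCM & pl$end > startCM))
    stop("overlapping planted segment on the same haplotype pair")
  sel <- cohort@loci$chrom == chrom & cohort@loci$cM >= startCM &
         cohort@loci$cM < endCM
  cohort@alleles[hapB, sel] <- cohort@alleles[hapA, sel]
  cohort@plantedIBD <- rbind(pl, data.frame(hapA = hapA, hapB = hapB,
                                            chrom = chrom, start = startCM,
                                            end = endCM))
  cohort
}

#' Write ancestry tracts as BED-like TSV
#'
#' Columns: haplotype_id, chrom, start_cM, end_cM, ancestry, posterior.
#' Half-open cM intervals; posterior is 1.0 for simulator truth.
#'
#' @param x A [SimulatedCohort-class] or a tract data.frame.
#' @param path Output file.
#' @export
writeTractsBed <- function(x, path) {
  tr <- if (is(x, "SimulatedCohort")) tracts(x) else x
  out <- data.frame(haplotype_id = tr$hap, chrom = tr$chrom,
                    start_cM = tr$start, end_cM = tr$end,
                    ancestry = tr$ancestry, posterior = tr$posterior)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write painted haplotypes as phased VCF plus PLINK-style map
#'
#' Emits a minimal phased VCF (GT with "|", individual i = haplotypes 2i-1 and
#' 2i) and a 4-column .map (chrom, id, cM, bp) with bp = round(cM * 1e6).
#'
#' @param cohort A painted [SimulatedCohort-class].
#' @param vcfPath,mapPath Output files.
#' @export
writeCohortVCF <- function(cohort, vcfPath, mapPath = NULL) {
  if (is.null(cohort@alleles)) stop("cohort has no painted alleles")
  al <- cohort@alleles
  loci <- cohort@loci
  n <- nIndividuals(cohort)
  ids <- sprintf("ind%d", seq_len(n))
  bp <- as.integer(round(loci$cM * 1e6))
  gt <- matrix(sprintf("%d|%d", t(al[seq(1, 2 * n, 2), , drop = FALSE]),
                       t(al[seq(2, 2 * n, 2), , drop = FALSE])),
               nrow = ncol(al), ncol = n)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=admixtract simulator (synthetic data)",
           paste0("##contig=<ID=", chromNames(cohort@chroms), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- cbind(loci$chrom, bp, sprintf("snp%d", seq_len(nrow(loci))),
                "A", "T", ".", "PASS", ".", "GT", gt)
  con <- file(vcfPath, "w")
  writeLines(hdr, con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  if (!is.null(mapPath)) {
    write.table(data.frame(loci$chrom, sprintf("snp%d", seq_len(nrow(loci))),
                           loci$cM, bp),
                mapPath, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(vcfPath)
}

#' Write simulation ground truth for test harnesses
#'
#' Schedule as JSON and planted IBD segments as TSV, alongside the tract BED.
#'
#' @param cohort A [SimulatedCohort-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohortTruth <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sj <- file.path(dir, "schedule.json")
  jsonlite::write_json(list(populations = populations(cohort@schedule),
                            m = migrationMatrix(cohort@schedule),
                            seed = cohort@seed),
                       sj, digits = NA)
  pt <- file.path(dir, "planted_ibd.tsv")
  write.table(cohort@plantedIBD, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- file.path(dir, "tracts.bed")
  writeTractsBed(cohort, tb)
  invisible(c(schedule = sj, planted = pt, tracts = tb))
}
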