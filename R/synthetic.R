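# Seeded synthetic venom-gland data with planted ground truth.
#
# The generator emulates the inputs of an integrated venomics study:
# toxin precursor transcripts (signal peptide + acidic propeptide ending
# in a processing quadruplet + cysteine-rich mature domain realizing a
# superfamily pattern), decoy housekeeping-like transcripts, TPM
# abundances from simulated counts, per-fraction MALDI neutral-mass lists
# (fully-oxidized acid forms, optionally the amidated form 0.98402 Da
# lighter), and carbamidomethylated tryptic MS/MS fragments with missed
# cleavages. Every planted quantity is recorded so each pipeline stage
# can be scored exactly.

#' Generator configuration
#'
#' @param n_toxin_genes Number of toxin precursor genes (default 26, the
#'   size of the catalogued cysteine-rich set the defaults emulate).
#' @param superfamily_mix Named numeric vector of proportions over the
#'   superfamily scheme (must sum to 1). Default: proportional to the
#'   observed member counts 1,1,2,4,2,6,2,8 over SF1..SF8.
#' @param amidation_fraction Fraction of mature peptides whose amidated
#'   form also appears in the MALDI lists (default 0.5).
#' @param mass_noise_sd Gaussian noise on observed masses, Da (default
#'   0.02, reflector-mode MALDI).
#' @param missed_cleavages Maximum missed tryptic cleavages (default 2).
#' @param utr_len_range Length range of the untranslated regions
#'   flanking each coding sequence (default 30-120 nt).
#' @param seed Integer seed fixing all randomness (default 1).
#' @param decoy_fraction Decoy (non-toxin) transcripts as a fraction of
#'   \code{n_toxin_genes} (default 0.1).
#' @param n_fractions Number of chromatographic fractions for the MALDI
#'   simulation (default 5).
#' @param expression_meanlog,expression_sdlog Log-normal parameters for
#'   simulated toxin counts (defaults 6 and 1; venom-gland toxin
#'   transcripts are strongly expressed). Decoys use
#'   \code{expression_meanlog - 3}.
#' @param min_fragment_len Shortest tryptic fragment reported (default 5
#'   residues; shorter peptides are not usefully sequenced by MS/MS).
#' @return List of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(n_toxin_genes = 26L, superfamily_mix = NULL,
                            amidation_fraction = 0.5, mass_noise_sd = 0.02,
                            missed_cleavages = 2L,
                            utr_len_range = c(30L, 120L), seed = 1L,
                            decoy_fraction = 0.1, n_fractions = 5L,
                            expression_meanlog = 6, expression_sdlog = 1,
                            min_fragment_len = 5L) {
  if (is.null(superfamily_mix)) {
    counts <- c(SF1 = 1, SF2 = 1, SF3 = 2, SF4 = 4, SF5 = 2, SF6 = 6,
                SF7 = 2, SF8 = 8)
    superfamily_mix <- counts / sum(counts)
  }
  if (abs(sum(superfamily_mix) - 1) > 1e-9)
    stop("superfamily_mix proportions must sum to 1")
  if (mass_noise_sd < 0) stop("mass_noise_sd must be >= 0")
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  if (amidation_fraction < 0 || amidation_fraction > 1)
    stop("amidation_fraction must be in [0, 1]")
  structure(list(
    n_toxin_genes = as.integer(n_toxin_genes),
    superfamily_mix = superfamily_mix,
    amidation_fraction = amidation_fraction,
    mass_noise_sd = mass_noise_sd,
    missed_cleavages = as.integer(missed_cleavages),
    utr_len_range = as.integer(utr_len_range),
    seed = as.integer(seed),
    decoy_fraction = decoy_fraction,
    n_fractions = as.integer(n_fractions),
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    min_fragment_len = as.integer(min_fragment_len)), class = "GeneratorConfig")
}

.NON_C <- setdiff(.AA20, "C")
.NON_CR <- setdiff(.AA20, c("C", "R"))
# acidic/polar residues for propeptides: no R (reserved for the PQM), no C,
# no hydrophobics (spider-toxin propeptides are Glu-rich and hydrophilic)
.PRO_BODY <- c("E", "D", "S", "N", "Q", "P", "G", "T")
# decoy alphabet: hydrophilic, no C and no strongly hydrophobic residues,
# so decoys carry neither frameworks nor signal-like h-regions
.DECOY_AA <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P", "H", "Y", "W")

.encodeProtein <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- .CODONS[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

.randomUtr <- function(len, forbid_atg = FALSE) {
  if (len <= 0L) return("")
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  if (forbid_atg) while (grepl("ATG", s, fixed = TRUE))
    s <- gsub("ATG", "ACG", s, fixed = TRUE)
  s
}

#' Generate one toxin precursor gene with planted truth
#'
#' Builds a precursor protein (hydrophobic signal peptide with a
#' small-residue cleavage context, acidic propeptide ending in a
#' processing quadruplet, cysteine-rich mature domain realizing the
#' superfamily's canonical pattern within its length range), encodes it
#' with random synonymous codons, and flanks it with UTRs (the 5' UTR is
#' kept free of ATG so the planted start is the first in-frame
#' methionine).
#'
#' @param sf One row of \code{\link{superfamilyDefinitions}()} (data.frame
#'   or list with \code{superfamily}, \code{canonical}, \code{len_min},
#'   \code{len_max}).
#' @param cfg A \code{\link{generatorConfig}} (UTR lengths).
#' @return List with \code{transcript} (DNA string), \code{protein},
#'   \code{signal}, \code{propeptide}, \code{mature},
#'   \code{superfamily}.
#' @export
generatePrecursorGene <- function(sf, cfg = generatorConfig()) {
  canonical <- sf$canonical
  runs <- strsplit(canonical, "-", fixed = TRUE)[[1]]
  if (!all(grepl("^C+$", runs))) stop("invalid canonical pattern: ", canonical)
  n_cys <- sum(nchar(runs))
  n_sep <- length(runs) - 1L
  min_needed <- n_cys + n_sep
  len_min <- max(sf$len_min, min_needed)
  if (len_min > sf$len_max)
    stop("length range too small to realize pattern ", canonical)
  # signal: M + charged + hydrophobic core + small-residue c-region (AQA)
  core_len <- sample(8:12, 1L)
  signal <- paste0("M", sample(c("K", "R"), 1L),
                   paste(sample(c("L", "V", "A", "I", "F"), core_len,
                                replace = TRUE), collapse = ""),
                   "AQA")
  # propeptide: acidic body then the processing quadruplet ...E-x-x-R
  body_len <- sample(3:9, 1L)
  propeptide <- paste0(
    paste(sample(.PRO_BODY, body_len, replace = TRUE), collapse = ""),
    "E", paste(sample(setdiff(.PRO_BODY, "E"), 2L, replace = TRUE),
               collapse = ""), "R")
  # mature: distribute spare residues over prefix, inter-cysteine gaps, tail
  L <- if (len_min >= sf$len_max) len_min else sample(len_min:sf$len_max, 1L)
  extra <- L - min_needed
  slots <- n_sep + 2L
  alloc <- tabulate(sample.int(slots, extra, replace = TRUE), nbins = slots)
  gaps <- alloc[2:(n_sep + 1L)] + 1L  # separators need >= 1 residue
  piece <- function(n, letters) if (n <= 0L) ""
    else paste(sample(letters, n, replace = TRUE), collapse = "")
  mature <- piece(alloc[1L], .NON_CR)  # no R before the first cysteine
  for (k in seq_along(runs)) {
    mature <- paste0(mature, runs[k])
    if (k <= n_sep) mature <- paste0(mature, piece(gaps[k], .NON_C))
  }
  mature <- paste0(mature, piece(alloc[slots], .NON_C))
  stopifnot(nchar(mature) == L)
  protein <- paste0(signal, propeptide, mature)
  utr5 <- .randomUtr(sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], 1L),
                     forbid_atg = TRUE)
  utr3 <- .randomUtr(sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], 1L))
  stop_codon <- .CODONS[["*"]][sample.int(3L, 1L)]
  transcript <- paste0(utr5, .encodeProtein(protein), stop_codon, utr3)
  list(transcript = transcript, protein = protein, signal = signal,
       propeptide = propeptide, mature = mature,
       superfamily = sf$superfamily)
}

.decoyGene <- function(cfg) {
  len <- sample(120:250, 1L)
  protein <- paste0("M", paste(sample(.DECOY_AA, len - 1L, replace = TRUE),
                               collapse = ""))
  utr5 <- .randomUtr(sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], 1L),
                     forbid_atg = TRUE)
  utr3 <- .randomUtr(sample(cfg$utr_len_range[1]:cfg$utr_len_range[2], 1L))
  paste0(utr5, .encodeProtein(protein), .CODONS[["*"]][sample.int(3L, 1L)],
         utr3)
}

#' Generate a synthetic venom-gland transcriptome with planted truth
#'
#' Produces toxin precursor transcripts according to the configured
#' superfamily mix, decoy transcripts, and TPM abundances computed from
#' simulated counts as \code{1e6 * (c_i/l_i) / sum_j (c_j/l_j)}.
#'
#' @param cfg A \code{\link{generatorConfig}}.
#' @return List with \code{transcripts} (\link[Biostrings]{DNAStringSet}
#'   with \code{abundance} metadata column, TPM) and \code{truth}
#'   (\link[S4Vectors]{DataFrame}: \code{transcript_id},
#'   \code{superfamily}, \code{signal}, \code{propeptide}, \code{mature},
#'   \code{mass_acid}, \code{mass_amide} (both fully oxidized),
#'   \code{amidated}, \code{tpm}).
#' @examples
#' bundle <- generateTranscriptome(generatorConfig(n_toxin_genes = 4, seed = 7))
#' length(bundle$transcripts)
#' @export
generateTranscriptome <- function(cfg = generatorConfig()) {
  set.seed(cfg$seed)
  defs <- superfamilyDefinitions()
  mix <- cfg$superfamily_mix
  if (!all(names(mix) %in% defs$superfamily))
    stop("superfamily_mix names not in the definition scheme")
  # deterministic composition: largest-remainder apportionment of n genes
  n <- cfg$n_toxin_genes
  quota <- mix * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra_order <- order(quota - base, decreasing = TRUE)
    base[extra_order[seq_len(rem)]] <- base[extra_order[seq_len(rem)]] + 1
  }
  sfs <- rep(names(mix), times = base)
  genes <- lapply(seq_along(sfs), function(i) {
    sf <- defs[defs$superfamily == sfs[i], , drop = FALSE]
    g <- generatePrecursorGene(as.list(sf), cfg)
    g$transcript_id <- sprintf("tox%04d", i)
    g
  })
  n_decoy <- ceiling(cfg$decoy_fraction * n)
  decoys <- if (n_decoy > 0) vapply(seq_len(n_decoy), function(i)
    .decoyGene(cfg), character(1)) else character(0)
  seqs <- c(vapply(genes, `[[`, character(1), "transcript"), decoys)
  ids <- c(vapply(genes, `[[`, character(1), "transcript_id"),
           if (n_decoy > 0) sprintf("dec%04d", seq_len(n_decoy)) else character(0))
  lens <- nchar(seqs)
  meanlogs <- c(rep(cfg$expression_meanlog, length(genes)),
                rep(cfg$expression_meanlog - 3, n_decoy))
  counts <- stats::rlnorm(length(seqs), meanlog = meanlogs,
                          sdlog = cfg$expression_sdlog)
  rate <- counts / lens
  tpm <- 1e6 * rate / sum(rate)
  transcripts <- Biostrings::DNAStringSet(seqs)
  names(transcripts) <- ids
  S4Vectors::mcols(transcripts) <- S4Vectors::DataFrame(abundance = tpm)
  amidated <- stats::runif(length(genes)) < cfg$amidation_fraction
  truth <- S4Vectors::DataFrame(
    transcript_id = vapply(genes, `[[`, character(1), "transcript_id"),
    superfamily = vapply(genes, `[[`, character(1), "superfamily"),
    signal = vapply(genes, `[[`, character(1), "signal"),
    propeptide = vapply(genes, `[[`, character(1), "propeptide"),
    mature = vapply(genes, `[[`, character(1), "mature"),
    mass_acid = vapply(genes, function(g)
      peptideMass(g$mature, oxidizedModificationSet(g$mature)$mods),
      numeric(1)),
    mass_amide = vapply(genes, function(g)
      peptideMass(g$mature, oxidizedModificationSet(g$mature, TRUE)$mods),
      numeric(1)),
    amidated = amidated,
    tpm = tpm[seq_along(genes)])
  list(transcripts = transcripts, truth = truth)
}

#' Simulate per-fraction MALDI neutral-mass lists
#'
#' Each mature peptide contributes its fully-oxidized acid mass to its
#' fraction; peptides flagged amidated in the truth table also contribute
#' the amide form (0.98402 Da lighter). Gaussian noise of
#' \code{cfg$mass_noise_sd} Da is added to every observation.
#'
#' @param truth Truth table from \code{\link{generateTranscriptome}}.
#' @param cfg A \code{\link{generatorConfig}}.
#' @return List with \code{observed} (data.frame: \code{fraction_id},
#'   \code{neutral_mass}) and \code{planted} (data.frame of planted acid /
#'   amide masses and fractions per gene).
#' @export
simulateMaldi <- function(truth, cfg = generatorConfig()) {
  set.seed(cfg$seed + 1L)
  n <- nrow(truth)
  frac <- sprintf("F%d", ((seq_len(n) - 1L) %% cfg$n_fractions) + 1L)
  planted <- data.frame(
    transcript_id = truth$transcript_id, fraction_id = frac,
    mass_acid = truth$mass_acid, mass_amide = truth$mass_amide,
    amidated = truth$amidated, stringsAsFactors = FALSE)
  obs <- data.frame(
    fraction_id = c(frac, frac[truth$amidated]),
    neutral_mass = c(truth$mass_acid, truth$mass_amide[truth$amidated]),
    stringsAsFactors = FALSE)
  obs$neutral_mass <- obs$neutral_mass +
    stats::rnorm(nrow(obs), sd = cfg$mass_noise_sd)
  ord <- order(obs$fraction_id, obs$neutral_mass)
  obs <- obs[ord, , drop = FALSE]
  rownames(obs) <- NULL
  list(observed = obs, planted = planted)
}

#' In silico tryptic digest
#'
#' Cleaves after K or R except when the next residue is P, and emits all
#' peptides with at most \code{missed} missed cleavage sites.
#'
#' @param seq Protein/peptide string.
#' @param missed Maximum missed cleavages (default 2).
#' @return data.frame with \code{sequence}, \code{start}, \code{end}
#'   (0-based half-open within \code{seq}), \code{missed},
#'   \code{flank_n}, \code{flank_c} (\code{"-"} at the termini).
#' @examples
#' digestTryptic("IFECVFSCDIEKEGKPCKPKG", missed = 2)$sequence
#' @export
digestTryptic <- function(seq, missed = 2L) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P" |
                           cut_after == n]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)  # 0-based ends
  bounds <- unique(bounds)
  rows <- list()
  n_seg <- length(bounds) - 1L
  for (i in seq_len(n_seg)) {
    for (j in i:min(n_seg, i + missed)) {
      s <- bounds[i]; e <- bounds[j + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = substr(seq, s + 1L, e), start = s, end = e,
        missed = j - i,
        flank_n = if (s == 0L) "-" else aa[s],
        flank_c = if (e == n) "-" else aa[e + 1L],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate carbamidomethylated tryptic MS/MS fragments
#'
#' Digests every planted mature peptide with
#' \code{\link{digestTryptic}} (up to \code{cfg$missed_cleavages} missed
#' sites), drops fragments shorter than \code{cfg$min_fragment_len},
#' computes m/z with all cysteines carbamidomethylated, and records the
#' flanking residues in dot notation.
#'
#' @param truth Truth table from \code{\link{generateTranscriptome}}.
#' @param cfg A \code{\link{generatorConfig}}.
#' @return data.frame with \code{id}, \code{transcript_id},
#'   \code{sequence}, \code{start}, \code{end} (0-based within the mature
#'   peptide), \code{mz}, \code{z}, \code{flank_n}, \code{flank_c},
#'   \code{notation} (e.g. \code{"K.IFECVFSCDIEK.E"}).
#' @export
simulateTrypticFragments <- function(truth, cfg = generatorConfig()) {
  set.seed(cfg$seed + 2L)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    d <- digestTryptic(truth$mature[i], missed = cfg$missed_cleavages)
    d <- d[nchar(d$sequence) >= cfg$min_fragment_len, , drop = FALSE]
    if (!nrow(d)) next
    nc <- vapply(gregexpr("C", d$sequence, fixed = TRUE),
                 function(g) sum(g > 0L), integer(1))
    z <- 1L + (nchar(d$sequence) >= 8L) + (nchar(d$sequence) >= 16L)
    m <- vapply(seq_len(nrow(d)), function(k)
      peptideMass(d$sequence[k],
                  modificationSet(carbamidomethyl = nc[k])), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("%s_t%02d", truth$transcript_id[i], seq_len(nrow(d))),
      transcript_id = truth$transcript_id[i],
      sequence = d$sequence, start = d$start, end = d$end,
      mz = mz(m, z), z = z, flank_n = d$flank_n, flank_c = d$flank_c,
      notation = paste0(d$flank_n, ".", d$sequence, ".", d$flank_c),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(id = character(0), transcript_id = character(0),
                      sequence = character(0), start = integer(0),
                      end = integer(0), mz = numeric(0), z = integer(0),
                      flank_n = character(0), flank_c = character(0),
                      notation = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
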