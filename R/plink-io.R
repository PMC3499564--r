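# PLINK 1.x binary I/O (hand-rolled codec: magic 0x6C 0x1B, SNP-major mode
# 0x01, 2-bit genotype codes with 0b01 = missing), phenotype TSV, the YAML
# run-configuration reader, and the command-line surface.

# 2-bit code -> dosage of allele A1: 00 = 2, 10 = 1, 11 = 0, 01 = NA
.PLINK_CODE_TO_DOSAGE <- c(2L, NA_integer_, 1L, 0L)   # index = code + 1
.PLINK_DOSAGE_TO_CODE <- c(3L, 2L, 0L)                # index = dosage + 1

#' Write a PLINK 1.x binary fileset
#'
#' Writes \code{<prefix>.bed} (magic bytes 0x6C 0x1B, SNP-major mode 0x01,
#' 2-bit codes, 0b01 = missing), \code{<prefix>.bim} and
#' \code{<prefix>.fam}. Dosages count the A1 allele.
#'
#' @param prefix output path prefix.
#' @param X n x m dosage matrix with values in \{0, 1, 2, NA\}.
#' @param variantIds variant identifiers (default snp1..snpm).
#' @param positions base-pair positions written to the .bim (default
#'   1..m, defining the genomic order).
#' @param sampleIds individual identifiers (default ind1..indn).
#' @return the prefix, invisibly.
#' @examples
#' pfx <- file.path(tempdir(), "toy")
#' writePlink(pfx, matrix(c(0, 1, 2, NA), 2, 2))
#' readPlink(pfx)$X
#' @export
writePlink <- function(prefix, X, variantIds = NULL, positions = NULL,
                       sampleIds = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (any(!is.na(X) & !(X %in% 0:2)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(variantIds)) variantIds <- sprintf("snp%d", seq_len(m))
  if (is.null(positions)) positions <- seq_len(m)
  if (is.null(sampleIds)) sampleIds <- sprintf("ind%d", seq_len(n))
  codes <- matrix(1L, n, m)        # 0b01 = missing
  ok <- !is.na(X)
  codes[ok] <- .PLINK_DOSAGE_TO_CODE[X[ok] + 1L]
  bytesPerSnp <- (n + 3L) %/% 4L
  pay <- raw(2L + 1L + bytesPerSnp * m)
  pay[1:3] <- as.raw(c(0x6C, 0x1B, 0x01))
  at <- 3L
  shift <- c(1L, 4L, 16L, 64L)     # 2-bit slots within a byte
  for (j in seq_len(m)) {
    v <- integer(bytesPerSnp)
    idx <- (seq_len(n) - 1L) %/% 4L + 1L
    slot <- (seq_len(n) - 1L) %% 4L + 1L
    contrib <- codes[, j] * shift[slot]
    v <- as.integer(rowsum(contrib, idx))
    pay[(at + 1L):(at + bytesPerSnp)] <- as.raw(v)
    at <- at + bytesPerSnp
  }
  writeBin(pay, paste0(prefix, ".bed"))
  bim <- data.frame(chrom = 1L, id = variantIds, cm = 0L, pos = positions,
                    a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = sampleIds, iid = sampleIds, father = 0L,
                    mother = 0L, sex = 0L, pheno = -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK 1.x binary fileset
#'
#' @param prefix path prefix, or pass the three paths explicitly.
#' @param bed,bim,fam explicit file paths (default \code{<prefix>.bed} etc.).
#' @return list with \code{X} (n x m dosages of A1 with NA for missing),
#'   \code{variantIds}, \code{positions}, \code{sampleIds} and
#'   \code{snpOrder} (rank order of the .bim positions).
#' @examples
#' pfx <- file.path(tempdir(), "toy2")
#' writePlink(pfx, matrix(c(0, 1, 2, 0), 2, 2))
#' str(readPlink(pfx)$X)
#' @export
readPlink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    if (is.null(bed)) bed <- paste0(prefix, ".bed")
    if (is.null(bim)) bim <- paste0(prefix, ".bim")
    if (is.null(fam)) fam <- paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam)) if (!file.exists(f))
    stop(sprintf("file not found: %s", f))
  bimTab <- utils::read.table(bim, header = FALSE,
                              col.names = c("chrom", "id", "cm", "pos",
                                            "a1", "a2"),
                              colClasses = c("character", "character",
                                             "numeric", "numeric",
                                             "character", "character"))
  famTab <- utils::read.table(fam, header = FALSE,
                              colClasses = "character")
  n <- nrow(famTab); m <- nrow(bimTab)
  pay <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(pay) < 3L || pay[1] != as.raw(0x6C) || pay[2] != as.raw(0x1B))
    stop("not a PLINK .bed file: magic bytes mismatch")
  if (pay[3] != as.raw(0x01))
    stop("only SNP-major (mode 0x01) .bed files are supported")
  bytesPerSnp <- (n + 3L) %/% 4L
  if (length(pay) != 3L + bytesPerSnp * m)
    stop(sprintf("truncated or oversized .bed payload: expected %d bytes, found %d",
                 3L + bytesPerSnp * m, length(pay) - 0L))
  body <- as.integer(pay[-(1:3)])
  X <- matrix(NA_integer_, n, m)
  idx <- (seq_len(n) - 1L) %/% 4L + 1L
  sh <- 2L * ((seq_len(n) - 1L) %% 4L)
  for (j in seq_len(m)) {
    bytes <- body[((j - 1L) * bytesPerSnp + 1L):(j * bytesPerSnp)]
    code <- bitwAnd(bitwShiftR(bytes[idx], sh), 3L)
    X[, j] <- .PLINK_CODE_TO_DOSAGE[code + 1L]
  }
  colnames(X) <- bimTab$id
  list(X = X, variantIds = bimTab$id, positions = bimTab$pos,
       sampleIds = famTab[[2L]], snpOrder = rank(bimTab$pos,
                                                 ties.method = "first"))
}

#' Write / read a phenotype TSV (FID, IID, value)
#'
#' @param path file path.
#' @param y phenotype values.
#' @param sampleIds individual identifiers (default ind1..indn).
#' @return \code{writePhenotypeTsv}: the path, invisibly;
#'   \code{readPhenotypeTsv}: list with \code{y} and \code{sampleIds}.
#' @examples
#' p <- file.path(tempdir(), "pheno.tsv")
#' writePhenotypeTsv(p, rnorm(3))
#' readPhenotypeTsv(p)$y
#' @export
writePhenotypeTsv <- function(path, y, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- sprintf("ind%d", seq_along(y))
  utils::write.table(data.frame(FID = sampleIds, IID = sampleIds, value = y),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeTsv
#' @export
readPhenotypeTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("FID", "IID", "value") %in% names(tab)))
    stop("phenotype TSV must have columns FID, IID, value")
  list(y = as.numeric(tab$value), sampleIds = as.character(tab$IID))
}

# ---- configuration files ---------------------------------------------------

.CONFIG_KEYS <- list(
  top = c("data", "prior", "sampler", "adaptation", "seed", "output_dir"),
  data = c("bed", "bim", "fam", "prefix", "phenotype"),
  prior = c("nu_sigma", "s2_sigma", "nu_s", "s2_s", "mu_xi", "sigma2_xi",
            "a_pi", "b_pi", "expected_associations"),
  sampler = c("type", "iterations", "thin", "burnin_fraction",
              "hyper_update_interval", "block_k", "k_max", "dr_cutoff",
              "eps_min", "p_geom_init", "kernel_weights",
              "neighborhood_cutoff", "p_swap", "p_neighborhood",
              "fixed_tau2", "dr_audit"),
  adaptation = c("adaptive", "adapt_move_size", "rb_interval",
                 "weight_interval", "move_size_interval"))

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")))
  invisible(x)
}

#' Read a YAML run-configuration file
#'
#' Schema-validated: unknown keys at any level are rejected. Sections:
#' \code{data} (PLINK \code{prefix} or \code{bed}/\code{bim}/\code{fam},
#' and \code{phenotype} TSV), \code{prior}, \code{sampler},
#' \code{adaptation}, plus top-level \code{seed} and \code{output_dir}.
#'
#' @param path YAML file path.
#' @param m number of variants, required only when the prior uses
#'   \code{expected_associations} and no data section is read here.
#' @return list with \code{data} (paths), \code{prior}
#'   (a \code{\linkS4class{PriorSpec}} or the raw list when it needs m),
#'   \code{config} (a \code{\linkS4class{RunConfig}}) and
#'   \code{outputDir}.
#' @examples
#' f <- file.path(tempdir(), "cfg.yaml")
#' writeLines(c("sampler:", "  type: msdr", "  iterations: 500",
#'              "seed: 3"), f)
#' readRunConfigFile(f)$config@sampler
#' @export
readRunConfigFile <- function(path, m = NULL) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must be a YAML mapping")
  .checkKeys(cfg, .CONFIG_KEYS$top, "top-level")
  dataSec <- cfg$data
  if (!is.null(dataSec)) .checkKeys(dataSec, .CONFIG_KEYS$data, "data")
  pr <- cfg$prior
  if (!is.null(pr)) .checkKeys(pr, .CONFIG_KEYS$prior, "prior")
  sm <- cfg$sampler
  if (!is.null(sm)) .checkKeys(sm, .CONFIG_KEYS$sampler, "sampler")
  ad <- cfg$adaptation
  if (!is.null(ad)) .checkKeys(ad, .CONFIG_KEYS$adaptation, "adaptation")

  pick <- function(lst, key, default) {
    if (is.null(lst[[key]])) default else lst[[key]]
  }
  prior <- if (!is.null(pr) && !is.null(pr$expected_associations) &&
               is.null(m)) {
    pr  # resolved later, once m is known
  } else {
    priorSpec(nuSigma = pick(pr, "nu_sigma", 1),
              s2Sigma = pick(pr, "s2_sigma", 1),
              nuS = pick(pr, "nu_s", 1), s2S = pick(pr, "s2_s", 0.1),
              muXi = pick(pr, "mu_xi", 1),
              sigma2Xi = pick(pr, "sigma2_xi", 1),
              aPi = pick(pr, "a_pi", 1),
              bPi = pick(pr, "b_pi", NULL),
              expectedAssociations = pick(pr, "expected_associations", NULL),
              m = m)
  }
  config <- runConfig(
    iterations = pick(sm, "iterations", 10000L),
    thin = pick(sm, "thin", 10L),
    burninFraction = pick(sm, "burnin_fraction", 0.5),
    hyperUpdateInterval = pick(sm, "hyper_update_interval", NULL),
    sampler = pick(sm, "type", "ms"),
    blockK = pick(sm, "block_k", 2L),
    kernelWeights = as.numeric(pick(sm, "kernel_weights", c(1, 0, 0))),
    kMax = pick(sm, "k_max", 20L),
    drCutoff = pick(sm, "dr_cutoff", 10L),
    epsMin = pick(sm, "eps_min", NULL),
    pGeomInit = pick(sm, "p_geom_init", 0.5),
    adaptive = pick(ad, "adaptive", TRUE),
    adaptMoveSize = pick(ad, "adapt_move_size", NULL),
    rbInterval = pick(ad, "rb_interval", 100L),
    weightInterval = pick(ad, "weight_interval", 1000L),
    moveSizeInterval = pick(ad, "move_size_interval", 5000L),
    neighborhoodCutoff = pick(sm, "neighborhood_cutoff", 20L),
    pSwap = pick(sm, "p_swap", 0.5),
    pNeighborhood = pick(sm, "p_neighborhood", 0.5),
    fixedTau2 = as.numeric(pick(sm, "fixed_tau2", numeric(0))),
    drAudit = pick(sm, "dr_audit", FALSE),
    seed = pick(cfg, "seed", 1L))
  list(data = dataSec, prior = prior, config = config,
       outputDir = pick(cfg, "output_dir", "."))
}

# ---- command-line surface --------------------------------------------------

# parse "--key value" pairs into a named list (flags repeated = error)
.parseArgs <- function(argv, allowed) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument: %s", a))
    key <- substring(a, 3L)
    if (!key %in% allowed)
      stop(sprintf("unknown option --%s (allowed: %s)", key,
                   paste(paste0("--", allowed), collapse = " ")))
    if (i == length(argv)) stop(sprintf("option --%s needs a value", key))
    if (!is.null(out[[key]])) stop(sprintf("option --%s given twice", key))
    out[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  out
}

.cliLoadData <- function(opts) {
  pl <- readPlink(prefix = opts$prefix, bed = opts$bed, bim = opts$bim,
                  fam = opts$fam)
  ph <- readPhenotypeTsv(opts$phenotype)
  if (length(ph$y) != nrow(pl$X))
    stop(sprintf("phenotype has %d individuals but genotypes have %d",
                 length(ph$y), nrow(pl$X)))
  gwasData(pl$X, ph$y, snpOrder = pl$snpOrder, variantIds = pl$variantIds)
}

.cliSimulate <- function(argv) {
  opts <- .parseArgs(argv, c("out", "n", "m", "ld-block-length", "rho",
                             "n-causal", "effect-scale", "pve", "seed",
                             "pair-trap"))
  if (is.null(opts$out)) stop("simulate needs --out <prefix>")
  seed <- as.integer(if (is.null(opts$seed)) 1L else opts$seed)
  num <- function(key, default) as.numeric(
    if (is.null(opts[[key]])) default else opts[[key]])
  if (identical(opts[["pair-trap"]], "true")) {
    trap <- makePairTrap(n = as.integer(num("n", 2000)),
                         m = as.integer(num("m", 200)), seed = seed)
    X <- trap$X; y <- trap$y; truth <- trap$truth
  } else {
    sp <- simSpec(n = as.integer(num("n", 2000)),
                  m = as.integer(num("m", 200)),
                  ldBlockLength = as.integer(num("ld-block-length", 20)),
                  rho = num("rho", 0.9),
                  nCausal = as.integer(num("n-causal", 5)),
                  effectScale = num("effect-scale", 0.3),
                  pve = num("pve", 0.5))
    X <- simulateGenotypes(sp, seed)
    sim <- simulatePhenotype(X, sp, seed + 1L)
    y <- sim$y; truth <- sim$truth
  }
  writePlink(opts$out, X)
  writePhenotypeTsv(paste0(opts$out, ".pheno.tsv"), y)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             paste0(opts$out, ".truth.json"))
  message(sprintf("wrote %s.{bed,bim,fam,pheno.tsv,truth.json}", opts$out))
  0L
}

.cliRun <- function(argv) {
  opts <- .parseArgs(argv, c("config", "seed", "sampler", "block-k",
                             "iterations", "thin", "out"))
  if (is.null(opts$config)) stop("run needs --config <yaml>")
  cf <- readRunConfigFile(opts$config)
  if (is.null(cf$data)) stop("config must have a data section for `run`")
  gd <- .cliLoadData(cf$data)
  prior <- if (is(cf$prior, "PriorSpec")) cf$prior else
    priorSpec(aPi = if (is.null(cf$prior$a_pi)) 1 else cf$prior$a_pi,
              expectedAssociations = cf$prior$expected_associations,
              m = nVariants(gd))
  cfg <- cf$config
  if (!is.null(opts$sampler)) {
    if (!opts$sampler %in% c("ss", "ms", "msdr", "ksc", "nk"))
      stop(sprintf("unknown sampler: %s", opts$sampler))
    cfg@sampler <- opts$sampler
  }
  if (!is.null(opts$seed)) cfg@seed <- as.integer(opts$seed)
  if (!is.null(opts[["block-k"]])) cfg@blockK <- as.integer(opts[["block-k"]])
  if (!is.null(opts$iterations)) cfg@iterations <- as.integer(opts$iterations)
  if (!is.null(opts$thin)) cfg@thin <- as.integer(opts$thin)
  methods::validObject(cfg)
  outDir <- if (is.null(opts$out)) cf$outputDir else opts$out
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tr <- runChain(gd, prior, cfg)
  file.copy(opts$config, file.path(outDir, "config.yaml"), overwrite = TRUE)
  # structured log: one line per 1000 iterations, from the records
  mr <- tr@moveRecords
  logAt <- if (nrow(mr) >= 1000L) seq(1000L, nrow(mr), by = 1000L)
           else nrow(mr)
  logLines <- vapply(logAt, function(i) {
    k <- max(1L, i %/% cfg@thin)
    sprintf("iter=%d logpost=%.4f size=%d moverate=%.4f", i,
            tr@logPost[min(k, length(tr@logPost))],
            as.integer(tr@modelSize[min(k, length(tr@modelSize))]),
            mean(mr$jump[seq_len(i)] > 0))
  }, character(1))
  writeLines(logLines, file.path(outDir, "run.log"))
  utils::write.table(data.frame(iteration = seq_len(length(tr@modelSize)) *
                                  cfg@thin,
                                modelSize = tr@modelSize,
                                logPost = tr@logPost, sigma2 = tr@sigma2,
                                xi = tr@xi, pve = tr@pve),
                     file.path(outDir, "scalars.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tr@moveRecords, file.path(outDir, "moves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(variant = gd@variantIds,
                                pipRB = tr@pipRB,
                                pipEmpirical = tr@pipEmpirical),
                     file.path(outDir, "pip.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gz <- gzfile(file.path(outDir, "gamma.tsv.gz"), "w")
  utils::write.table(tr@gammaTrace, gz, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(gz)
  eff <- chainEfficiency(tr)
  writeLines(jsonlite::toJSON(c(eff, list(psHashCount = length(tr@psHash),
                                          burninKept = tr@burninKept)),
                              auto_unbox = TRUE, digits = NA),
             file.path(outDir, "report.json"))
  message(sprintf("run finished: %d kept samples, outputs in %s",
                  length(tr@modelSize), outDir))
  0L
}

.cliDiagnose <- function(argv) {
  opts <- .parseArgs(argv, c("dir", "out"))
  if (is.null(opts$dir)) stop("diagnose needs --dir <run output dir>")
  scal <- utils::read.table(file.path(opts$dir, "scalars.tsv"),
                            header = TRUE, sep = "\t")
  moves <- utils::read.table(file.path(opts$dir, "moves.tsv"),
                             header = TRUE, sep = "\t")
  gam <- as.matrix(utils::read.table(
    gzfile(file.path(opts$dir, "gamma.tsv.gz")), sep = "\t"))
  stats <- moveStatistics(moves)
  essMs <- geyerEss(scal$modelSize)
  ham <- rowSums(abs(diff(gam)))
  essHam <- if (stats::var(ham) == 0)
    list(act = 1, ess = length(ham)) else geyerEss(ham)
  report <- c(stats, list(
    essModelSize = essMs$ess, actModelSize = essMs$act,
    essHamming = essHam$ess, actHamming = essHam$act,
    essLogPost = geyerEss(scal$logPost)$ess,
    essPve = geyerEss(scal$pve)$ess))
  tabLines <- c(
    sprintf("%-12s %8s %8s %10s %10s", "sampler", "RJD", "PJD",
            "RJD/PJD", "Move rate"),
    sprintf("%-12s %8.3f %8.3f %10.3f %10.3f", "(records)", stats$rjd,
            stats$pjd, stats$rjdOverPjd, stats$moveRate))
  outPath <- if (is.null(opts$out)) file.path(opts$dir, "diagnostics.json")
  else opts$out
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
             outPath)
  writeLines(tabLines, sub("\\.json$", ".txt", outPath))
  message(paste(tabLines, collapse = "\n"))
  0L
}

.cliEnumerate <- function(argv) {
  opts <- .parseArgs(argv, c("prefix", "bed", "bim", "fam", "phenotype",
                             "tau2", "out"))
  gd <- .cliLoadData(opts)
  if (nVariants(gd) > 20L) stop("enumeration is limited to m <= 20")
  tau2 <- as.numeric(if (is.null(opts$tau2)) 1 else opts$tau2)
  enum <- enumeratePosterior(gd, priorSpec(), tau2 = tau2)
  out <- list(pip = enum$pip, sizeProb = unname(enum$sizeProb),
              topModels = lapply(order(enum$prob, decreasing = TRUE)[1:10],
                                 function(i) list(variants = enum$models[[i]],
                                                  prob = enum$prob[i])))
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (is.null(opts$out)) cat(js, "\n") else writeLines(js, opts$out)
  0L
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write a synthetic PLINK fileset, phenotype
#' TSV and truth JSON), \code{run} (YAML config to traces and reports, with
#' \code{--seed}, \code{--sampler}, \code{--block-k}, \code{--iterations},
#' \code{--thin} overrides), \code{diagnose} (run outputs to an ESS /
#' move-statistics report) and \code{enumerate} (small-m exact posterior).
#'
#' @param argv character vector of arguments (subcommand first); defaults
#'   to the process arguments.
#' @return integer exit code (0 on success; errors raise conditions, which
#'   the installed script maps to a nonzero exit with the message).
#' @examples
#' pfx <- file.path(tempdir(), "cli-ex")
#' runGwasCli(c("simulate", "--out", pfx, "--n", "60", "--m", "8",
#'              "--seed", "3"))
#' @export
runGwasCli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L)
    stop("usage: <simulate|run|diagnose|enumerate> [--options]; see ?runGwasCli")
  sub <- argv[1L]; rest <- argv[-1L]
  switch(sub,
         simulate = .cliSimulate(rest),
         run = .cliRun(rest),
         diagnose = .cliDiagnose(rest),
         enumerate = .cliEnumerate(rest),
         stop(sprintf("unknown subcommand: %s (expected simulate, run, diagnose or enumerate)",
                      sub)))
}
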