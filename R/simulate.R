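#' Simulation configuration
#'
#' Defines the structure of a simulated multi-species latitudinal
#' expression study: negative-binomial read counts for replicate pools of
#' two focal populations (a high-latitude "Maine" role and a low-latitude
#' "Panama" role) and optionally two outgroup populations, for one or two
#' tissues, in two or three species, with planted latitudinal log2 effects
#' that are correlated across species through their 1:1 orthologs.
#'
#' The default configuration mirrors a three-species, two-tissue,
#' two-population design with three replicate pools per cell and two
#' outgroup populations for branch-length rooting.
#'
#' @param n_genes genes per species.
#' @param species_list 2 or 3 species labels.
#' @param tissues tissue labels to simulate.
#' @param populations named pair \code{c(low = ..., high = ...)} giving the
#'   low- and high-latitude focal population labels.
#' @param outgroups two outgroup population labels (used when
#'   \code{include_outgroups} is \code{TRUE}).
#' @param include_outgroups generate outgroup populations for rooting.
#' @param n_replicates replicate pools per species x population x tissue.
#' @param baseline_log_mean_range range (log2 scale) of baseline expression
#'   drawn uniformly per gene.
#' @param dispersion negative-binomial dispersion phi; counts have variance
#'   \eqn{\mu + \phi \mu^2} (the NB size parameter is \code{1/dispersion});
#'   0 gives Poisson counts.
#' @param effect_sd SD of the planted latitudinal log2 effects.
#' @param cross_species_corr correlation of true latitudinal effects between
#'   species across orthologs (equicorrelation; for 3 species must be
#'   >= -0.5 for positive semidefiniteness).
#' @param shared_outlier_fraction fraction of ortholog rows given an
#'   additional large effect with common sign across species.
#' @param outlier_effect magnitude (log2) of the shared outlier effect.
#' @param de_direction_bias probability that a planted effect is negative,
#'   i.e. lower in the low-latitude population. At the default 0.5 the
#'   correlated normal draws are left untouched; away from 0.5 each
#'   ortholog row's common sign is resampled with this probability.
#' @param class_enrichment named numeric vector mapping gene-class label to
#'   the relative risk of membership among affected genes (genes whose
#'   maximal absolute planted effect is at least \code{effect_sd}).
#' @param class_base_rate baseline membership probability per class.
#' @param ortholog_coverage fraction of genes placed in the ortholog map.
#' @param outgroup_drift_sd SD of the independent normal log2 drift of each
#'   outgroup population from the ancestral (baseline) mean.
#' @param library_size_range range of per-sample library sizes (reads).
#' @param gene_length_range range of transcript lengths (bp).
#' @param seed master seed; per-species RNG streams are derived from it by
#'   fixed offsets so that adding a species does not perturb another
#'   species' draws.
#' @return an object of class \code{SimConfig}.
#' @export
simConfig <- function(n_genes = 8000,
                      species_list = c("Dmel", "Dsim", "Dhyd"),
                      tissues = c("AG", "testis"),
                      populations = c(low = "Panama", high = "Maine"),
                      outgroups = c("Madagascar", "Zimbabwe"),
                      include_outgroups = TRUE,
                      n_replicates = 3,
                      baseline_log_mean_range = c(0, 8),
                      dispersion = 0.005,
                      effect_sd = 0.5,
                      cross_species_corr = 0.46,
                      shared_outlier_fraction = 0.02,
                      outlier_effect = 2,
                      de_direction_bias = 0.5,
                      class_enrichment = c(Sfp = 3.5),
                      class_base_rate = 0.03,
                      ortholog_coverage = 0.8,
                      outgroup_drift_sd = 0.3,
                      library_size_range = c(5e6, 1.5e7),
                      gene_length_range = c(500, 5000),
                      seed = 1L) {
    cfg <- list(n_genes = as.integer(n_genes),
                species_list = as.character(species_list),
                tissues = as.character(tissues),
                populations = populations,
                outgroups = as.character(outgroups),
                include_outgroups = isTRUE(include_outgroups),
                n_replicates = as.integer(n_replicates),
                baseline_log_mean_range = as.numeric(baseline_log_mean_range),
                dispersion = as.numeric(dispersion),
                effect_sd = as.numeric(effect_sd),
                cross_species_corr = as.numeric(cross_species_corr),
                shared_outlier_fraction = as.numeric(shared_outlier_fraction),
                outlier_effect = as.numeric(outlier_effect),
                de_direction_bias = as.numeric(de_direction_bias),
                class_enrichment = class_enrichment,
                class_base_rate = as.numeric(class_base_rate),
                ortholog_coverage = as.numeric(ortholog_coverage),
                outgroup_drift_sd = as.numeric(outgroup_drift_sd),
                library_size_range = as.numeric(library_size_range),
                gene_length_range = as.numeric(gene_length_range),
                seed = as.integer(seed))
    validateSimConfig(cfg)
    class(cfg) <- "SimConfig"
    cfg
}

validateSimConfig <- function(cfg) {
    k <- length(cfg$species_list)
    if (cfg$n_genes < 1L) stop("n_genes must be positive")
    if (k < 2L || k > 3L) stop("species_list must name 2 or 3 species")
    if (cfg$n_replicates < 1L) stop("n_replicates must be positive")
    if (cfg$dispersion < 0) stop("dispersion must be non-negative")
    if (cfg$effect_sd < 0) stop("effect_sd must be non-negative")
    if (abs(cfg$cross_species_corr) > 1)
        stop("cross_species_corr must be in [-1, 1]")
    if (k == 3L && cfg$cross_species_corr < -0.5)
        stop("cross_species_corr = ", cfg$cross_species_corr,
             " is incompatible with a positive semidefinite 3-species ",
             "correlation matrix (requires >= -0.5)")
    for (p in c("shared_outlier_fraction", "de_direction_bias",
                "class_base_rate"))
        if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
    if (cfg$ortholog_coverage <= 0 || cfg$ortholog_coverage > 1)
        stop("ortholog_coverage must be in (0, 1]")
    if (cfg$outgroup_drift_sd < 0) stop("outgroup_drift_sd must be >= 0")
    if (any(diff(cfg$baseline_log_mean_range) < 0) ||
        any(diff(cfg$library_size_range) < 0) ||
        any(diff(cfg$gene_length_range) < 0))
        stop("ranges must be ordered (min, max)")
    if (any(cfg$library_size_range <= 0)) stop("library sizes must be > 0")
    if (!all(c("low", "high") %in% names(cfg$populations)))
        stop("populations must be a named pair c(low = ..., high = ...)")
    invisible(TRUE)
}

## Evaluate a function with a private RNG stream, restoring the caller's
## RNG state afterwards so simulation is side-effect free.
with_rng <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

## Shared (cross-species) draws: ortholog effect normals mixed through the
## nested Cholesky factor of the equicorrelation matrix, shared-outlier rows
## and signs. Always drawn as an n x 3 block so the first two species'
## columns are identical whether or not a third species is simulated.
draw_shared <- function(cfg, nOrth) {
    with_rng(cfg$seed + 77L, {
        out <- list()
        for (t in cfg$tissues) {
            z <- matrix(rnorm(nOrth * 3L), nOrth, 3L)
            nOut <- round(cfg$shared_outlier_fraction * nOrth)
            rows <- if (nOut > 0) sample.int(nOrth, nOut) else integer(0)
            signs <- if (nOut > 0)
                ifelse(runif(nOut) < cfg$de_direction_bias, -1, 1)
            else numeric(0)
            rowSigns <- if (cfg$de_direction_bias != 0.5)
                ifelse(runif(nOrth) < cfg$de_direction_bias, -1, 1)
            else NULL
            out[[t]] <- list(z = z, outlierRows = rows,
                             outlierSigns = signs, rowSigns = rowSigns)
        }
        out
    })
}

#' Simulate a multi-species latitudinal expression dataset
#'
#' Generates per-species \linkS4class{CountsDataset}s, an
#' \linkS4class{OrthologMap}, per-species gene-class
#' \linkS4class{GeneSet}s and a ground-truth table, following the design
#' in the supplied \code{\link{simConfig}}. Counts are negative-binomial
#' with gene means given by library-size-scaled expected TPM; true
#' latitudinal log2 effects are equicorrelated across species over
#' orthologs; a configurable fraction of ortholog rows receives a large
#' common-sign outlier effect; outgroup populations drift independently
#' from the ancestral mean. The same configuration (including seed) always
#' yields identical output.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return a list with elements \code{counts} (named list of
#'   \linkS4class{CountsDataset}, one per species), \code{orthologs}
#'   (\linkS4class{OrthologMap}), \code{geneSets} (list of
#'   \linkS4class{GeneSet}), \code{truth} (data.frame with columns
#'   \code{species}, \code{tissue}, \code{gene_id},
#'   \code{true_log2_effect}, \code{ortholog_row}, \code{classes}) and
#'   \code{config}.
#' @examples
#' sim <- simulateDataset(simConfig(n_genes = 200, species_list =
#'   c("A", "B"), tissues = "AG", include_outgroups = FALSE, seed = 7))
#' sim$counts$A
#' @export
simulateDataset <- function(config) {
    if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
    cfg <- config
    k <- length(cfg$species_list)
    nG <- cfg$n_genes
    nOrth <- max(1L, round(cfg$ortholog_coverage * nG))
    nPriv <- nG - nOrth

    Rk <- matrix(cfg$cross_species_corr, k, k)
    diag(Rk) <- 1
    U <- chol(Rk)                       # upper; nested in species order
    shared <- draw_shared(cfg, nOrth)

    lowPop <- cfg$populations[["low"]]
    highPop <- cfg$populations[["high"]]
    pops <- c(highPop, lowPop)
    if (cfg$include_outgroups) pops <- c(pops, cfg$outgroups)

    countsList <- list()
    truthList <- list()
    geneSets <- list()
    geneLists <- vector("list", k)

    for (i in seq_len(k)) {
        sp <- cfg$species_list[i]
        genes <- paste0(sp, "_g", seq_len(nG))
        geneLists[[i]] <- genes[seq_len(nOrth)]
        res <- with_rng(cfg$seed + 1000L * i, {
            lens <- round(runif(nG, cfg$gene_length_range[1],
                                cfg$gene_length_range[2]))
            baseline <- matrix(runif(nG * length(cfg$tissues),
                                     cfg$baseline_log_mean_range[1],
                                     cfg$baseline_log_mean_range[2]),
                               nG, dimnames = list(genes, cfg$tissues))
            eff <- matrix(0, nG, length(cfg$tissues),
                          dimnames = list(genes, cfg$tissues))
            for (t in cfg$tissues) {
                sh <- shared[[t]]
                eOrth <- cfg$effect_sd *
                    drop(sh$z[, seq_len(k), drop = FALSE] %*% U[, i])
                if (!is.null(sh$rowSigns))
                    eOrth <- sh$rowSigns * abs(eOrth)
                if (length(sh$outlierRows))
                    eOrth[sh$outlierRows] <- eOrth[sh$outlierRows] +
                        sh$outlierSigns * cfg$outlier_effect
                ePriv <- if (nPriv > 0) rnorm(nPriv, 0, cfg$effect_sd)
                         else numeric(0)
                if (cfg$de_direction_bias != 0.5 && nPriv > 0)
                    ePriv <- ifelse(runif(nPriv) < cfg$de_direction_bias,
                                    -1, 1) * abs(ePriv)
                eff[, t] <- c(eOrth, ePriv)
            }
            drift <- list()
            for (t in cfg$tissues)
                drift[[t]] <- vapply(cfg$outgroups, function(o)
                    rnorm(nG, 0, cfg$outgroup_drift_sd),
                    numeric(nG))
            affected <- apply(abs(eff), 1, max) >= max(cfg$effect_sd, 1e-12)
            memb <- list()
            for (lab in names(cfg$class_enrichment)) {
                rr <- cfg$class_enrichment[[lab]]
                p <- ifelse(affected,
                            pmin(1, rr * cfg$class_base_rate),
                            cfg$class_base_rate)
                memb[[lab]] <- runif(nG) < p
            }
            ## count generation, in fixed sample order
            cols <- list()
            info <- list()
            lenKb <- lens / 1000
            for (t in cfg$tissues) {
                for (p in pops) {
                    logmu <- baseline[, t]
                    if (p == lowPop) logmu <- logmu + eff[, t]
                    if (p %in% cfg$outgroups)
                        logmu <- logmu + drift[[t]][, p]
                    a <- 2^logmu
                    frac <- a * lenKb / sum(a * lenKb)
                    for (r in seq_len(cfg$n_replicates)) {
                        L <- round(runif(1, cfg$library_size_range[1],
                                         cfg$library_size_range[2]))
                        mu <- L * frac
                        y <- if (cfg$dispersion > 0)
                            rnbinom(nG, mu = mu, size = 1 / cfg$dispersion)
                        else rpois(nG, mu)
                        id <- paste(sp, t, p, r, sep = "_")
                        cols[[id]] <- y
                        info[[id]] <- data.frame(
                            sample_id = id, species = sp, population = p,
                            tissue = t, replicate = r)
                    }
                }
            }
            list(lens = lens, eff = eff, memb = memb, cols = cols,
                 info = info)
        })
        m <- do.call(cbind, res$cols)
        rownames(m) <- genes
        countsList[[sp]] <- CountsDataset(m, res$lens,
                                          do.call(rbind, res$info))
        membMat <- do.call(cbind, res$memb)
        classes <- if (is.null(membMat) || ncol(membMat) == 0)
            rep("", nG)
        else apply(membMat, 1, function(z)
            paste(colnames(membMat)[z], collapse = ";"))
        for (lab in names(cfg$class_enrichment)) {
            ids <- genes[res$memb[[lab]]]
            if (length(ids))
                geneSets[[paste(lab, sp, sep = ".")]] <-
                    GeneSet(ids, label = lab, species = sp)
        }
        for (t in cfg$tissues)
            truthList[[paste(sp, t)]] <- data.frame(
                species = sp, tissue = t, gene_id = genes,
                true_log2_effect = res$eff[, t],
                ortholog_row = c(seq_len(nOrth), rep(NA_integer_, nPriv)),
                classes = classes, stringsAsFactors = FALSE)
    }

    omap <- OrthologMap(setNames(as.data.frame(geneLists),
                                 cfg$species_list))
    truth <- do.call(rbind, truthList)
    rownames(truth) <- NULL
    list(counts = countsList, orthologs = omap, geneSets = geneSets,
         truth = truth, config = cfg)
}

#' Write a simulated dataset to a fixture directory
#'
#' Runs \code{\link{simulateDataset}} and writes every TSV consumed by the
#' package readers (per-species counts, lengths and metadata, the ortholog
#' map, one file per gene set), plus the ground-truth table and the
#' configuration as YAML. Two calls with the same configuration produce
#' byte-identical files.
#'
#' @param config a \code{\link{simConfig}}.
#' @param outDir output directory (created if absent).
#' @return data.frame manifest with columns \code{type} and \code{file}.
#' @export
emitFixture <- function(config, outDir) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    sim <- simulateDataset(config)
    manifest <- list()
    add <- function(type, file) manifest[[length(manifest) + 1L]] <<-
        data.frame(type = type, file = file)
    for (sp in names(sim$counts)) {
        fc <- file.path(outDir, paste0("counts_", sp, ".tsv"))
        fm <- file.path(outDir, paste0("metadata_", sp, ".tsv"))
        fl <- file.path(outDir, paste0("lengths_", sp, ".tsv"))
        writeCounts(sim$counts[[sp]], fc, fm, fl)
        add("counts", fc); add("metadata", fm); add("lengths", fl)
    }
    fo <- file.path(outDir, "orthologs.tsv")
    writeOrthologMap(sim$orthologs, fo)
    add("orthologs", fo)
    for (nm in names(sim$geneSets)) {
        gs <- sim$geneSets[[nm]]
        fg <- file.path(outDir, paste0("geneset_", geneSetLabel(gs), "_",
                                       geneSetSpecies(gs), ".tsv"))
        writeGeneSet(gs, fg)
        add("gene_set", fg)
    }
    ft <- file.path(outDir, "truth.tsv")
    tr <- sim$truth
    tr$true_log2_effect <- fmt_num(tr$true_log2_effect)
    write_tsv(tr, ft)
    add("truth", ft)
    fy <- file.path(outDir, "config.yaml")
    yaml::write_yaml(unclass(sim$config), fy)
    add("config", fy)
    do.call(rbind, manifest)
}
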