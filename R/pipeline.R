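#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end analysis: the DE
#' adjusted-P cutoff (default 0.1), the strict median-TPM expression
#' threshold (default 1), the tau cutoff for tissue bias (default 0.9),
#' the tissue-bias adjusted-P bound (default 0.01), and the focal /
#' outgroup population labels. Every default is overridable and all
#' values are logged at startup.
#'
#' @param alpha_de adjusted-P cutoff for latitudinal DE.
#' @param alpha_bias adjusted-P bound of the tissue-bias classifier.
#' @param tpm_threshold strict median-TPM expression threshold.
#' @param tau_cutoff tau cutoff for tissue-biased calls.
#' @param populations named pair \code{c(low = ..., high = ...)} of focal
#'   population labels.
#' @param outgroups outgroup population labels used for branch-length
#'   rooting.
#' @param prior_count log2-CPM prior count.
#' @return a \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(alpha_de = 0.1, alpha_bias = 0.01,
                           tpm_threshold = 1, tau_cutoff = 0.9,
                           populations = c(low = "Panama", high = "Maine"),
                           outgroups = c("Madagascar", "Zimbabwe"),
                           prior_count = 0.5) {
    stopifnot(alpha_de > 0, alpha_de <= 1, alpha_bias > 0, alpha_bias < 1,
              tpm_threshold >= 0, tau_cutoff >= 0, tau_cutoff <= 1,
              all(c("low", "high") %in% names(populations)))
    structure(list(alpha_de = alpha_de, alpha_bias = alpha_bias,
                   tpm_threshold = tpm_threshold, tau_cutoff = tau_cutoff,
                   populations = populations, outgroups = outgroups,
                   prior_count = prior_count),
              class = "PipelineConfig")
}

fmt_p <- function(p) ifelse(is.na(p), "NA", formatC(p, format = "e",
                                                    digits = 2))

stage_log <- function(...) message("[parallelCline] ", sprintf(...))

#' Run the full analysis on a dataset directory
#'
#' Orchestrates the end-to-end pipeline on a directory in the fixture
#' layout written by \code{\link{emitFixture}} (per-species counts,
#' lengths and metadata TSVs, an ortholog map, optional gene-set files):
#' per species x tissue latitudinal DE; cross-species parallelism for all
#' pairs (and the triple, when three species are present) per tissue;
#' branch-length decomposition for every species with outgroup samples;
#' and gene-class DE and directionality enrichment for every gene-set
#' file. The run is deterministic: identical inputs and configuration
#' give byte-identical reports.
#'
#' Five presentation tables are written (percentages to one decimal,
#' p-values to three significant figures) alongside full-precision
#' companions (suffix \code{_full}) and the per-contrast DE tables.
#'
#' @param dataDir input directory.
#' @param outDir output directory (created if absent).
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a named list of the report data.frames.
#' @export
runPipeline <- function(dataDir, outDir, config = pipelineConfig()) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    stage_log("config: alpha_de=%g tpm_threshold=%g alpha_bias=%g tau_cutoff=%g low=%s high=%s",
              config$alpha_de, config$tpm_threshold, config$alpha_bias,
              config$tau_cutoff, config$populations[["low"]],
              config$populations[["high"]])

    metaFiles <- list.files(dataDir, "^metadata_.*\\.tsv$",
                            full.names = TRUE)
    if (!length(metaFiles)) stop("no metadata_<species>.tsv in ", dataDir)
    species <- sub("^metadata_(.*)\\.tsv$", "\\1", basename(metaFiles))
    datasets <- lapply(species, function(sp)
        readCounts(file.path(dataDir, paste0("counts_", sp, ".tsv")),
                   file.path(dataDir, paste0("metadata_", sp, ".tsv")),
                   file.path(dataDir, paste0("lengths_", sp, ".tsv"))))
    names(datasets) <- species
    tissues <- sort(unique(unlist(lapply(datasets, function(d)
        sampleInfo(d)$tissue))))
    stage_log("stage=read species=%d tissues=%d",
              length(species), length(tissues))

    ## --- stage 1: latitudinal DE per species x tissue -------------------
    deTabs <- list()
    t1 <- list()
    for (sp in species) for (t in tissues) {
        de <- latitudinalDE(datasets[[sp]], sp, t,
                            populations = config$populations,
                            alpha = config$alpha_de,
                            tpmThreshold = config$tpm_threshold,
                            priorCount = config$prior_count)
        deTabs[[paste(sp, t)]] <- de
        writeDETable(de, file.path(outDir, paste0("de_", sp, "_", t,
                                                  ".tsv")))
        t1[[paste(sp, t)]] <- data.frame(
            species = sp, tissue = t, total_de = sum(de$is_de),
            expressed = attr(de, "n_expressed"),
            percent_de = percentDE(sum(de$is_de),
                                   attr(de, "n_expressed")))
        stage_log("stage=de species=%s tissue=%s in=%d expressed=%d de=%d",
                  sp, t, nrow(datasets[[sp]]), attr(de, "n_expressed"),
                  sum(de$is_de))
    }
    table1 <- do.call(rbind, t1); rownames(table1) <- NULL

    ## --- stage 2: parallelism per comparison x tissue -------------------
    omapPath <- file.path(dataDir, "orthologs.tsv")
    table2 <- table2full <- NULL
    if (file.exists(omapPath)) {
        otab <- read_tsv_checked(omapPath)
        comparisons <- utils::combn(species, 2, simplify = FALSE)
        if (length(species) == 3L)
            comparisons <- c(comparisons, list(species))
        t2 <- t2f <- list()
        for (cmp in comparisons) for (t in tissues) {
            if (!all(cmp %in% colnames(otab))) next
            map <- OrthologMap(otab[, cmp, drop = FALSE])
            prep <- parallelismReport(
                setNames(deTabs[paste(cmp, t)], cmp), map, tissue = t)
            row <- data.frame(
                species_1 = cmp[1], species_2 = cmp[2],
                species_3 = if (length(cmp) == 3) cmp[3] else "...",
                tissue = t, observed_shared_de = prep$k_obs,
                expected_shared_de = round(prep$expected_shared, 1),
                enrichment_p = fmt_p(prep$enrichment_p),
                pct_higher_in_maine =
                    round(prep$pct_higher_in_maine / 100, 3),
                pct_same_direction = round(prep$pct_same_direction_shared),
                pct_same_direction_all =
                    round(prep$pct_same_direction_all, 1),
                concordance_p = fmt_p(prep$concordance_p),
                spearman_rho = round(prep$spearman_rho, 2),
                spearman_p = fmt_p(prep$spearman_p))
            rowf <- row
            rowf$expected_shared_de <- prep$expected_shared
            rowf$enrichment_p <- prep$enrichment_p
            rowf$pct_higher_in_maine <- prep$pct_higher_in_maine
            rowf$pct_same_direction <- prep$pct_same_direction_shared
            rowf$pct_same_direction_all <- prep$pct_same_direction_all
            rowf$concordance_p <- prep$concordance_p
            rowf$spearman_rho <- prep$spearman_rho
            rowf$spearman_p <- prep$spearman_p
            key <- paste(paste(cmp, collapse = "-"), t)
            t2[[key]] <- row; t2f[[key]] <- rowf
            stage_log("stage=parallelism cmp=%s tissue=%s N=%d shared=%d",
                      paste(cmp, collapse = "/"), t, prep$N, prep$k_obs)
        }
        table2 <- do.call(rbind, t2); rownames(table2) <- NULL
        table2full <- do.call(rbind, t2f); rownames(table2full) <- NULL
    }

    ## --- stage 3: branch lengths for species with outgroup samples ------
    t3 <- t3f <- list()
    for (sp in species) {
        pops <- unique(sampleInfo(datasets[[sp]])$population)
        if (!all(config$outgroups %in% pops)) next
        tpm <- computeTpm(datasets[[sp]])
        for (t in tissues) {
            de <- deTabs[[paste(sp, t)]]
            led <- ledTable(tpm, sampleInfo(datasets[[sp]]), sp, t,
                            focal = unname(config$populations[c("high",
                                                                "low")]),
                            outgroups = config$outgroups,
                            genes = de$gene_id)
            deIds <- de$gene_id[de$is_de]
            ndIds <- de$gene_id[!de$is_de]
            focal <- attr(led, "focal")
            addRow <- function(label1, label2, ids1, ids2, pop) {
                tt <- ledTest(led, ids1, ids2, population = pop)
                data.frame(species = sp, tissue = t,
                           comparison = label1, versus = label2,
                           population = pop,
                           mean_led_1 = tt$mean1, mean_led_2 = tt$mean2,
                           t_test_p = tt$p)
            }
            rows <- list(addRow("All", "between populations", NULL, NULL,
                                paste(focal, collapse = " vs ")))
            if (length(deIds) >= 2 && length(ndIds) >= 2)
                for (p in focal)
                    rows[[length(rows) + 1L]] <-
                        addRow("DE", "not DE", deIds, ndIds, p)
            blk <- do.call(rbind, rows)
            t3f[[paste(sp, t)]] <- blk
            blkr <- blk
            blkr$mean_led_1 <- round(blk$mean_led_1, 4)
            blkr$mean_led_2 <- round(blk$mean_led_2, 4)
            blkr$t_test_p <- fmt_p(blk$t_test_p)
            t3[[paste(sp, t)]] <- blkr
            stage_log("stage=led species=%s tissue=%s genes=%d", sp, t,
                      nrow(led))
        }
    }
    table3 <- if (length(t3)) do.call(rbind, t3) else NULL
    table3full <- if (length(t3f)) do.call(rbind, t3f) else NULL
    if (!is.null(table3)) rownames(table3) <- NULL
    if (!is.null(table3full)) rownames(table3full) <- NULL

    ## --- stages 4-5: gene-class enrichment ------------------------------
    gsFiles <- list.files(dataDir, "^geneset_.*\\.tsv$", full.names = TRUE)
    t4 <- t4f <- t5 <- t5f <- list()
    for (f in gsFiles) {
        part <- strsplit(sub("^geneset_(.*)\\.tsv$", "\\1", basename(f)),
                         "_")[[1]]
        lab <- part[1]; sp <- paste(part[-1], collapse = "_")
        if (!(sp %in% species)) next
        gs <- readGeneSet(f, label = lab, species = sp)
        for (t in tissues) {
            de <- deTabs[[paste(sp, t)]]
            nExpr <- sum(de$gene_id %in% members(gs))
            if (nExpr == 0) next
            tab <- buildDETable(de, gs)
            fe <- fisherExact(tab)
            es <- enrichmentSummary(tab)
            key <- paste(lab, sp, t)
            t4f[[key]] <- data.frame(
                species = sp, tissue = t, class = lab,
                expressed_class = nExpr, class_de = tab$a,
                not_class_de = tab$b, class_not_de = tab$c,
                not_class_not_de = tab$d, total = tab$total,
                pct_class_de = es$pct_in, pct_class_not_de = es$pct_out,
                fisher_p = fe$p)
            r <- t4f[[key]]
            r$pct_class_de <- round(r$pct_class_de, 1)
            r$pct_class_not_de <- round(r$pct_class_not_de, 1)
            r$fisher_p <- fmt_p(r$fisher_p)
            t4[[key]] <- r
            dtab <- suppressWarnings(buildDirectionTable(de, gs))
            dfe <- fisherExact(dtab)
            t5f[[key]] <- data.frame(
                species = sp, tissue = t, class = lab,
                class_expressed = nExpr, class_pos_logfc = dtab$a,
                not_class_pos_logfc = dtab$b, class_neg_logfc = dtab$c,
                not_class_neg_logfc = dtab$d, total = dtab$total,
                pct_class_neg_logfc =
                    100 * dtab$c / (dtab$a + dtab$c),
                fisher_p = dfe$p)
            r <- t5f[[key]]
            r$pct_class_neg_logfc <- round(r$pct_class_neg_logfc, 1)
            r$fisher_p <- fmt_p(r$fisher_p)
            t5[[key]] <- r
            stage_log("stage=enrichment class=%s species=%s tissue=%s a=%d",
                      lab, sp, t, tab$a)
        }
    }
    bindOrNull <- function(x) if (length(x)) {
        out <- do.call(rbind, x); rownames(out) <- NULL; out
    } else NULL
    table4 <- bindOrNull(t4); table4full <- bindOrNull(t4f)
    table5 <- bindOrNull(t5); table5full <- bindOrNull(t5f)

    reports <- list(table1 = table1, table2 = table2, table3 = table3,
                    table4 = table4, table5 = table5,
                    table2_full = table2full, table3_full = table3full,
                    table4_full = table4full, table5_full = table5full)
    for (nm in names(reports))
        if (!is.null(reports[[nm]]))
            write_tsv(reports[[nm]], file.path(outDir,
                                               paste0(nm, ".tsv")))
    stage_log("stage=done tables=%d",
              sum(!vapply(reports, is.null, logical(1))))
    invisible(reports)
}
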