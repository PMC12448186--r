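## Small simulation configurations used across tests. Sizes are kept small
## where the property under test allows it; calibration-style tests state
## their own sizes.

small_config <- function(...) {
    defaults <- list(n_genes = 120, species_list = c("A", "B"),
                     tissues = "AG", include_outgroups = FALSE,
                     library_size_range = c(2e6, 4e6), seed = 42)
    args <- utils::modifyList(defaults, list(...))
    do.call(simConfig, args)
}

## A deterministic toy DE table for unit tests of downstream modules.
toy_de_table <- function(gene_ids, log_fc, p_adj,
                         is_de = p_adj <= 0.1, ave_expr = 5) {
    data.frame(gene_id = gene_ids, log_fc = log_fc, ave_expr = ave_expr,
               t_mod = 0, df_total = 10, p_raw = p_adj, p_adj = p_adj,
               is_de = is_de, stringsAsFactors = FALSE)
}
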