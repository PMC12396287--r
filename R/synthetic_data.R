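#' Planted-bridge graph specification
#'
#' Describes a two-community protein graph with known bridge nodes: a
#' target-side community containing the protein of interest, a query
#' community of DAP-like nodes, `n_bridges` true bridges each wired to
#' `bridge_degree_to_queries` queries and to the target, and `n_noise`
#' decoy nodes embedded in the target community but touching at most
#' `noise_max_query_links` queries.  Edge confidences are sampled uniformly
#' on `[score_threshold, 1]`.
#'
#' @param target_size nodes in the target community (the first one is the
#'   target protein).
#' @param n_queries number of query (DAP) nodes.
#' @param n_bridges number of planted bridge nodes.
#' @param bridge_degree_to_queries queries each bridge is wired to
#'   (default 5).
#' @param n_noise number of decoy nodes.
#' @param noise_max_query_links maximum query links per decoy (default 2).
#' @param p_in within-community edge probability (default 0.5).
#' @param p_out cross-community edge probability (default 0.02); must be
#'   below `p_in`.
#' @param score_threshold lower bound of sampled confidences (default 0.7).
#' @param plant_annotations give all bridges a shared term over a mixed
#'   background, for enrichment testing (default TRUE).
#' @param seed integer seed.
#' @return A list of class `planted_graph_spec`.
#' @export
planted_graph_spec <- function(target_size = 8, n_queries = 12, n_bridges = 3,
                               bridge_degree_to_queries = 5, n_noise = 5,
                               noise_max_query_links = 2, p_in = 0.5,
                               p_out = 0.02, score_threshold = 0.7,
                               plant_annotations = TRUE, seed = 1) {
  stopifnot(target_size >= 1, n_queries >= 1, n_bridges >= 0, n_noise >= 0,
            p_in > p_out, p_out >= 0, score_threshold >= 0,
            score_threshold < 1)
  structure(list(target_size = target_size, n_queries = n_queries,
                 n_bridges = n_bridges,
                 bridge_degree_to_queries = bridge_degree_to_queries,
                 n_noise = n_noise,
                 noise_max_query_links = noise_max_query_links,
                 p_in = p_in, p_out = p_out,
                 score_threshold = score_threshold,
                 plant_annotations = isTRUE(plant_annotations),
                 seed = as.integer(seed)),
            class = "planted_graph_spec")
}

# all unordered pairs of `ids` kept with probability p
random_pairs <- function(ids, p) {
  if (length(ids) < 2 || p <= 0) {
    return(data.frame(from = character(), to = character()))
  }
  cmb <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(cmb)) < p
  data.frame(from = cmb[1, keep], to = cmb[2, keep])
}

#' Generate a planted-bridge graph
#'
#' @param spec a [planted_graph_spec()].
#' @return List with `graph` (a [ppi_graph()]), `bridges` (ground-truth
#'   bridge ids), `queries`, `target`.
#' @export
make_planted_bridge_graph <- function(spec) {
  stopifnot(inherits(spec, "planted_graph_spec"))
  if (spec$bridge_degree_to_queries > spec$n_queries) {
    stop("bridge_degree_to_queries exceeds the number of query nodes")
  }
  if (spec$noise_max_query_links > spec$n_queries) {
    stop("noise_max_query_links exceeds the number of query nodes")
  }
  set.seed(spec$seed)
  tgt_comm <- sprintf("T%02d", seq_len(spec$target_size))
  target <- tgt_comm[1]
  queries <- sprintf("Q%02d", seq_len(spec$n_queries))
  bridges <- if (spec$n_bridges) sprintf("B%02d", seq_len(spec$n_bridges))
             else character()
  noise <- if (spec$n_noise) sprintf("N%02d", seq_len(spec$n_noise))
           else character()

  pieces <- list(
    random_pairs(tgt_comm, spec$p_in),
    random_pairs(queries, spec$p_in),
    if (spec$p_out > 0) {
      grid <- expand.grid(from = tgt_comm, to = queries,
                          stringsAsFactors = FALSE)
      grid[stats::runif(nrow(grid)) < spec$p_out, , drop = FALSE]
    }
  )
  for (b in bridges) {
    linked <- sample(queries, spec$bridge_degree_to_queries)
    pieces[[length(pieces) + 1L]] <- data.frame(from = b,
                                                to = c(target, linked))
  }
  for (nn in noise) {
    # decoys live in the target community and touch few queries
    comm <- tgt_comm[stats::runif(spec$target_size) < spec$p_in]
    if (!length(comm)) comm <- sample(tgt_comm, 1)
    q_links <- sample(queries, sample.int(spec$noise_max_query_links, 1))
    pieces[[length(pieces) + 1L]] <- data.frame(from = nn,
                                                to = c(comm, q_links))
  }
  edges <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  edges$weight <- stats::runif(nrow(edges), spec$score_threshold, 1)

  nodes <- c(tgt_comm, queries, bridges, noise)
  annotations <- list()
  if (spec$plant_annotations) {
    annotations <- stats::setNames(
      lapply(nodes, function(n) {
        base <- sample(c("GO:MIX1", "GO:MIX2"), 1)
        if (n %in% bridges) c(base, "GO:BRIDGE") else base
      }), nodes)
  }
  graph <- ppi_graph(edges, nodes = nodes, annotations = annotations,
                     score_threshold = spec$score_threshold)
  list(graph = graph, bridges = bridges, queries = queries, target = target)
}

#' qPCR Ct-table simulation spec
#'
#' Emulates a two-group qPCR experiment on the six-ISG interferon panel:
#' patient ISG cycle thresholds are shifted *down* by `isg_log2_shift`
#' cycles (lower Ct means higher expression, so the downstream relative
#' quantification is `2^shift`), housekeeping genes are identically
#' distributed in both groups, and Gaussian measurement noise of
#' `noise_sd` cycles is added to every well.
#'
#' @param n_per_group samples per group (default 8).
#' @param isg_log2_shift per-ISG downward Ct shift in patients; a scalar is
#'   recycled over the panel (default 3).
#' @param isg_baseline control-group ISG mean Ct (default 28).
#' @param housekeeping_baseline named mean Cts of the reference genes.
#' @param noise_sd Gaussian noise standard deviation in cycles
#'   (default 0.3).
#' @param isgs,housekeeping gene panels (defaults as in [score_panel()]).
#' @param seed integer seed.
#' @return A list of class `ct_sim_spec`.
#' @export
ct_sim_spec <- function(n_per_group = 8, isg_log2_shift = 3,
                        isg_baseline = 28,
                        housekeeping_baseline = c(GAPDH = 18, HPRT = 26,
                                                  PPIA = 22, RPL13A = 20),
                        noise_sd = 0.3,
                        isgs = c("IFIT1", "IFI27", "IFI44", "IFI44L",
                                 "ISG15", "MX1"),
                        housekeeping = names(housekeeping_baseline),
                        seed = 1) {
  stopifnot(n_per_group >= 1, noise_sd >= 0)
  shift <- rep_len(isg_log2_shift, length(isgs))
  names(shift) <- isgs
  structure(list(n_per_group = as.integer(n_per_group),
                 isg_log2_shift = shift, isg_baseline = isg_baseline,
                 housekeeping_baseline = housekeeping_baseline,
                 noise_sd = noise_sd, isgs = isgs,
                 housekeeping = housekeeping, seed = as.integer(seed)),
            class = "ct_sim_spec")
}

#' Simulate a long-format Ct table
#'
#' @param spec a [ct_sim_spec()].
#' @return data.frame with columns `sample`, `group`, `gene`, `ct`; the
#'   calibrator sample id (the first control) is in
#'   `attr(, "calibrator")`.
#' @export
make_ct_table <- function(spec) {
  stopifnot(inherits(spec, "ct_sim_spec"))
  set.seed(spec$seed)
  samples <- c(sprintf("control%02d", seq_len(spec$n_per_group)),
               sprintf("patient%02d", seq_len(spec$n_per_group)))
  groups <- rep(c("control", "patient"), each = spec$n_per_group)
  genes <- c(spec$isgs, spec$housekeeping)
  base <- c(stats::setNames(rep(spec$isg_baseline, length(spec$isgs)),
                            spec$isgs),
            spec$housekeeping_baseline[spec$housekeeping])
  rows <- expand.grid(gene = genes, sample_idx = seq_along(samples),
                      stringsAsFactors = FALSE)
  out <- data.frame(sample = samples[rows$sample_idx],
                    group = groups[rows$sample_idx],
                    gene = rows$gene)
  shift <- ifelse(out$group == "patient" & out$gene %in% spec$isgs,
                  spec$isg_log2_shift[out$gene], 0)
  shift[is.na(shift)] <- 0
  out$ct <- base[out$gene] - shift +
    stats::rnorm(nrow(out), sd = spec$noise_sd)
  rownames(out) <- NULL
  attr(out, "calibrator") <- samples[1]
  out
}

#' Cohort simulation spec
#'
#' Two variant-cluster groups with per-feature prevalences, masked to
#' not-assessed at a fixed rate.  Variants are generated so that group
#' membership matches the default [cluster_rule()] (group 1 residues in
#' 416-434, group 2 in 621-628).
#'
#' @param n_group1,n_group2 group sizes.
#' @param prevalence_group1,prevalence_group2 named per-feature prevalences
#'   in \[0, 1\] (same feature names in both).
#' @param not_assessed_rate probability a call is masked to `NA`.
#' @param seed integer seed.
#' @return A list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_group1 = 16, n_group2 = 24,
                            prevalence_group1 = c(severe_myopathy = 0.05,
                                                  lung_impairment = 0.15),
                            prevalence_group2 = c(severe_myopathy = 0.20,
                                                  lung_impairment = 0.50),
                            not_assessed_rate = 0.2, seed = 1) {
  stopifnot(n_group1 >= 1, n_group2 >= 1,
            identical(names(prevalence_group1), names(prevalence_group2)),
            all(prevalence_group1 >= 0 & prevalence_group1 <= 1),
            all(prevalence_group2 >= 0 & prevalence_group2 <= 1),
            not_assessed_rate >= 0, not_assessed_rate <= 1)
  structure(list(n_group1 = as.integer(n_group1),
                 n_group2 = as.integer(n_group2),
                 prevalence_group1 = prevalence_group1,
                 prevalence_group2 = prevalence_group2,
                 not_assessed_rate = not_assessed_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

# three-letter amino-acid codes used for simulated missense variants
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

#' Simulate a cohort table
#'
#' @param spec a [cohort_sim_spec()].
#' @return A [cohort_table()] (no literature aggregates).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_group1 + spec$n_group2
  grp <- rep(1:2, c(spec$n_group1, spec$n_group2))
  residues <- ifelse(grp == 1, sample(416:434, n, replace = TRUE),
                     sample(621:628, n, replace = TRUE))
  variants <- sprintf("p.(%s%d%s)", sample(AA3, n, replace = TRUE),
                      residues, sample(AA3, n, replace = TRUE))
  ind <- data.frame(id = sprintf("S%03d", seq_len(n)),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    age = sample(5:60, n, replace = TRUE),
                    protein_variant = variants,
                    inheritance = sample(c("de novo", "inherited"), n,
                                         replace = TRUE))
  for (f in names(spec$prevalence_group1)) {
    prev <- ifelse(grp == 1, spec$prevalence_group1[[f]],
                   spec$prevalence_group2[[f]])
    call <- stats::rbinom(n, 1, prev)
    call[stats::runif(n) < spec$not_assessed_rate] <- NA
    ind[[f]] <- call
  }
  cohort_table(ind)
}

#' Simulate paired DAP tables with a known truth set
#'
#' True DAPs receive a large |log2 fold-change| (Gaussian around
#' `true_lfc_mean` with a per-protein sign, consistent across tables) and a
#' small p-value in every table; null proteins get near-zero log2
#' fold-changes and uniform p-values.
#'
#' @param n_proteins total proteins per table.
#' @param frac_true fraction that are true DAPs in every table.
#' @param true_lfc_mean,true_lfc_sd |log2 fc| distribution of true DAPs.
#' @param null_lfc_sd log2 fc spread of null proteins.
#' @param true_p_max p-values of true DAPs are uniform on
#'   `[0, true_p_max]`.
#' @param n_tables number of tables (default 2).
#' @param seed integer seed.
#' @return List with `tables` (list of data.frames `protein`,
#'   `fold_change` on the log2 scale, `p_value`) and `truth` (character
#'   vector of true DAP ids).
#' @export
make_dap_tables <- function(n_proteins = 200, frac_true = 0.15,
                            true_lfc_mean = 2, true_lfc_sd = 0.3,
                            null_lfc_sd = 0.15, true_p_max = 0.01,
                            n_tables = 2, seed = 1) {
  stopifnot(n_proteins >= 1, frac_true >= 0, frac_true <= 1, n_tables >= 1)
  set.seed(seed)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  n_true <- round(frac_true * n_proteins)
  truth <- if (n_true) sort(sample(proteins, n_true)) else character()
  signs <- stats::setNames(sample(c(-1, 1), n_proteins, replace = TRUE),
                           proteins)
  tables <- lapply(seq_len(n_tables), function(i) {
    is_true <- proteins %in% truth
    lfc <- ifelse(is_true,
                  signs[proteins] * abs(stats::rnorm(n_proteins,
                                                     true_lfc_mean,
                                                     true_lfc_sd)),
                  stats::rnorm(n_proteins, 0, null_lfc_sd))
    p <- ifelse(is_true, stats::runif(n_proteins, 0, true_p_max),
                stats::runif(n_proteins))
    data.frame(protein = proteins, fold_change = lfc, p_value = p)
  })
  list(tables = tables, truth = truth)
}
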