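#' Pipeline configuration
#'
#' Assembles the resolved run configuration: input/output paths, cell types,
#' and every tunable. Values can come from a YAML file, with direct
#' arguments taking precedence (CLI > file > defaults).
#'
#' @param input_dir directory holding the input tables (layout of
#'   [write_fixture()])
#' @param out_dir output directory for all stage results
#' @param config_file optional YAML file with any of these keys
#' @param ... overrides for any default listed below
#' @return a validated `epictrees_config` list
#' @export
pipeline_config <- function(input_dir, out_dir, config_file = NULL, ...) {
  defaults <- list(
    input_dir = input_dir, out_dir = out_dir,
    cell_types = c("alpha", "beta", "acinar", "duct"),
    promoter_up = 2000L, promoter_down = 3000L,
    min_loop_length = 5000L, min_pet = 1,
    nearest_min_d = 5000L, nearest_max_d = 1e6L,
    ess_hi = 0.7, ess_lo = 0.3,
    folds = 10L, k_grid = seq(3L, 25L, 2L), n_reps = 100L,
    redraw_negatives = TRUE,
    gwas_threshold = 1e-4,
    seed = 1L)
  from_file <- if (!is.null(config_file)) yaml::read_yaml(config_file) else list()
  over <- list(...)
  cfg <- utils::modifyList(utils::modifyList(defaults, from_file), over)
  if (is.null(cfg$input_dir) || is.null(cfg$out_dir))
    stopf("input_dir and out_dir are required")
  structure(cfg, class = "epictrees_config")
}

missing_stage <- function(stage, needed) {
  stop(errorCondition(
    sprintf("outputs of stage '%s' not found in out_dir; run stage '%s' first", needed, needed),
    class = c("epictrees_missing_stage", "error"),
    stage = stage, needed = needed))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  path
}

trees_paths <- function(out_dir, ct) {
  file.path(out_dir, sprintf("trees_%s_%s.tsv", ct,
                             c("trees", "nodes", "edges", "pp", "orphans")))
}

write_trees <- function(tr, out_dir) {
  p <- trees_paths(out_dir, tr$cell_type)
  write_tsv(tr$trees, p[1]); write_tsv(tr$nodes, p[2]); write_tsv(tr$edges, p[3])
  write_tsv(tr$pp_edges, p[4])
  writeLines(tr$orphans, p[5])
  p
}

read_trees <- function(out_dir, ct, min_pet = 1) {
  p <- trees_paths(out_dir, ct)
  if (!all(file.exists(p))) return(NULL)
  structure(list(cell_type = ct,
                 trees = read.delim(p[1], stringsAsFactors = FALSE),
                 nodes = read.delim(p[2], stringsAsFactors = FALSE),
                 edges = read.delim(p[3], stringsAsFactors = FALSE),
                 pp_edges = read.delim(p[4], stringsAsFactors = FALSE),
                 orphans = readLines(p[5]), min_pet = min_pet),
            class = "enhancer_trees")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (`consensus`, `trees`, `annotate`,
#' `epic`, `snps`), reading inputs from `config$input_dir` and writing every
#' output plus a manifest (file checksums and the resolved configuration)
#' under `config$out_dir`. A stage run on its own requires its upstream
#' stage's outputs in `out_dir` and fails with an actionable error naming
#' the missing stage otherwise. No stage mutates its inputs.
#'
#' @param config an `epictrees_config` from [pipeline_config()]
#' @param stages which stages to run (default: all)
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(config,
                         stages = c("consensus", "trees", "annotate", "epic", "snps")) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- config
  cts <- cfg$cell_types
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  bundle <- read_fixture(cfg$input_dir)
  outputs <- character(0)
  note <- function(p) outputs <<- c(outputs, p)

  anchors <- loops <- atac <- NULL
  load_consensus <- function() {
    pa <- file.path(out, "consensus_anchors.tsv")
    pl <- file.path(out, "consensus_loops.tsv")
    pn <- file.path(out, "node_atac.tsv")
    if (!all(file.exists(c(pa, pl, pn)))) missing_stage("trees", "consensus")
    anchors <<- read.delim(pa, stringsAsFactors = FALSE)
    loops <<- read.delim(pl, stringsAsFactors = FALSE)
    atac <<- read.delim(pn, stringsAsFactors = FALSE)
  }

  if ("consensus" %in% stages) {
    all_anchor_ivs <- do.call(rbind, lapply(bundle$loops, loop_anchors))
    anchors <- build_consensus_anchors(all_anchor_ivs)
    anchors <- classify_anchors(anchors, bundle$genes,
                                up = cfg$promoter_up, down = cfg$promoter_down)
    loops <- build_consensus_loops(bundle$loops, anchors,
                                   min_length = cfg$min_loop_length)
    atac <- atac_by_node(anchors, bundle$peaks, cts)
    message(sprintf("consensus: %d anchors (%d P, %d E), %d loops (%d removed < %d bp)",
                    nrow(anchors), sum(anchors$node_kind == "P"),
                    sum(anchors$node_kind == "E"), nrow(loops),
                    attr(loops, "n_short_removed"), cfg$min_loop_length))
    note(write_tsv(anchors, file.path(out, "consensus_anchors.tsv")))
    note(write_tsv(loops, file.path(out, "consensus_loops.tsv")))
    note(write_tsv(atac, file.path(out, "node_atac.tsv")))
  }

  trees_by_ct <- NULL
  load_trees <- function(stage) {
    trees_by_ct <<- setNames(lapply(cts, function(ct)
      read_trees(out, ct, cfg$min_pet)), cts)
    if (any(vapply(trees_by_ct, is.null, TRUE))) missing_stage(stage, "trees")
  }

  if ("trees" %in% stages) {
    if (is.null(anchors)) load_consensus()
    trees_by_ct <- setNames(lapply(cts, function(ct)
      extract_trees(anchors, loops, ct, min_pet = cfg$min_pet)), cts)
    stats_all <- list()
    for (ct in cts) {
      tr <- trees_by_ct[[ct]]
      fo <- detect_forests(tr, anchors)
      st <- connectivity_stats(tr, fo)
      ppc <- pp_comparison(tr, fo, bundle$expression, ess_hi = cfg$ess_hi)
      st$pp_comparison <- ppc[c("median_specific", "median_other", "p_value")]
      stats_all[[ct]] <- st
      message(sprintf("trees[%s]: %d trees, %d forests, %d orphan enhancers",
                      ct, nrow(tr$trees), nrow(fo$forests), length(tr$orphans)))
      for (p in write_trees(tr, out)) note(p)
      note(write_tsv(fo$membership, file.path(out, paste0("forests_", ct, ".tsv"))))
      note(write_tsv(fo$forests, file.path(out, paste0("forest_stats_", ct, ".tsv"))))
      note(export_trees_graphml(tr, anchors, atac,
                                file.path(out, paste0("trees_", ct, ".graphml"))))
    }
    note(write_json_out(stats_all, file.path(out, "connectivity_stats.json")))
  }

  if ("annotate" %in% stages) {
    if (is.null(anchors)) load_consensus()
    if (is.null(trees_by_ct)) load_trees("annotate")
    chains <- do.call(rbind, lapply(cts, function(ct)
      extract_chains(trees_by_ct[[ct]], anchors, bundle$genes)))
    skip <- do.call(rbind, lapply(cts, function(ct)
      skipping_analysis(trees_by_ct[[ct]], anchors, bundle$genes,
                        bundle$expression, min_d = cfg$nearest_min_d,
                        max_d = cfg$nearest_max_d)))
    note(write_tsv(chains, file.path(out, "chains.tsv")))
    note(write_tsv(skip, file.path(out, "skipping.tsv")))
    ok <- !is.na(skip$skipped) & skip$skipped & !is.na(skip$orientation)
    counts <- table(skip$cell_type[ok], skip$orientation[ok])
    ann <- list(orientation_counts = as.data.frame.matrix(counts))
    if (nrow(counts) >= 2 && ncol(counts) >= 2 &&
        all(rowSums(counts) > 0) && all(colSums(counts) > 0))
      ann$orientation_chisq <- orientation_chisq(counts)
    ann$expression_vs_treesize <- lapply(cts, function(ct)
      expression_vs_treesize(trees_by_ct[[ct]], bundle$expression,
                             skip[skip$cell_type == ct, , drop = FALSE]))
    names(ann$expression_vs_treesize) <- cts
    note(write_json_out(ann, file.path(out, "annotation.json")))
  }

  effect_sizes <- NULL
  if ("epic" %in% stages) {
    if (is.null(anchors)) load_consensus()
    if (is.null(trees_by_ct)) load_trees("epic")
    tree_genes_by_ct <- lapply(trees_by_ct, function(tr) unique(tr$trees$gene_id))
    model_report <- list()
    for (ct in cts) {
      ts <- build_training_set(bundle$expression, ct, tree_genes_by_ct,
                               ess_hi = cfg$ess_hi, ess_lo = cfg$ess_lo,
                               seed = cfg$seed)
      if (nrow(ts) < 8) next
      X <- build_feature_matrix(ts$gene_id, trees_by_ct, atac)
      full <- train_and_evaluate(X, ts$class, folds = cfg$folds,
                                 k_grid = cfg$k_grid, seed = cfg$seed)
      direct <- train_and_evaluate(X[, grep("_d_", colnames(X)), drop = FALSE],
                                   ts$class, folds = cfg$folds,
                                   k_grid = cfg$k_grid, seed = cfg$seed,
                                   model_kind = "tree_direct_only")
      prom <- baseline_promoter_only(ts$gene_id, ts$class, anchors, atac, cts,
                                     folds = cfg$folds, k_grid = cfg$k_grid,
                                     seed = cfg$seed)
      lin <- baseline_linear(ts$gene_id, ts$class, bundle$genes, anchors, atac,
                             cts, folds = cfg$folds, k_grid = cfg$k_grid,
                             seed = cfg$seed)
      model_report[[ct]] <- lapply(list(full, direct, prom, lin), function(m)
        list(model_kind = m$model_kind, k = m$k, cv_accuracy = m$cv_accuracy,
             n = length(m$prob)))
      Xp <- X; attr(Xp, "caches") <- NULL
      note(write_tsv(cbind(ts, as.data.frame(Xp)),
                     file.path(out, paste0("features_", ct, ".tsv"))))
      message(sprintf("epic[%s]: n = %d, tree %.3f | direct %.3f | promoter %.3f | linear %.3f",
                      ct, nrow(ts), full$cv_accuracy, direct$cv_accuracy,
                      prom$cv_accuracy, lin$cv_accuracy))
    }
    note(write_json_out(model_report, file.path(out, "epic_models.json")))
    es <- epic_effect_sizes(trees_by_ct, atac, bundle$expression,
                            n_reps = cfg$n_reps, folds = cfg$folds,
                            k_grid = cfg$k_grid, ess_hi = cfg$ess_hi,
                            ess_lo = cfg$ess_lo, seed = cfg$seed,
                            redraw_negatives = cfg$redraw_negatives)
    effect_sizes <- rank_enhancers(es)
    note(write_tsv(effect_sizes, file.path(out, "effect_sizes.tsv")))
  }

  if ("snps" %in% stages) {
    if (is.null(anchors)) load_consensus()
    if (is.null(trees_by_ct)) load_trees("snps")
    if (is.null(effect_sizes)) {
      pe <- file.path(out, "effect_sizes.tsv")
      if (!file.exists(pe)) missing_stage("snps", "epic")
      effect_sizes <- read.delim(pe, stringsAsFactors = FALSE)
    }
    links <- intersect_snps(bundle$snps, trees_by_ct, anchors,
                            gwas_threshold = cfg$gwas_threshold)
    note(write_tsv(links, file.path(out, "snp_links.tsv")))
    strat <- list()
    for (ct in cts) {
      s <- stratify_effect_sizes(links, effect_sizes, ct)
      strat[[ct]] <- s[c("D", "p_value", "flag")]
      strat[[ct]]$n_overlapping <- length(s$overlapping)
      strat[[ct]]$n_other <- length(s$other)
    }
    note(write_json_out(strat, file.path(out, "snp_stratification.json")))
    for (p in export_enrichment_annotations(bundle$snps, trees_by_ct, anchors,
                                            file.path(out, "enrichment")))
      note(p)
  }

  input_files <- list.files(cfg$input_dir, full.names = TRUE)
  manifest <- list(
    config = unclass(cfg),
    stages = stages,
    inputs = as.list(tools::md5sum(sort(input_files))),
    outputs = as.list(setNames(unname(tools::md5sum(sort(unique(outputs)))),
                               basename(sort(unique(outputs))))))
  names(manifest$inputs) <- basename(sort(input_files))
  write_json_out(manifest, file.path(out, "run_manifest.json"))
  invisible(manifest)
}

#' Export a tree set as GraphML for network-visualisation tools
#'
#' Nodes carry kind, level (minimum over trees), and per-cell-type ATAC;
#' edges carry the PET count.
#'
#' @param tr an `enhancer_trees` object
#' @param anchors classified consensus anchors
#' @param atac node accessibility table
#' @param path output file
#' @return `path`, invisibly
#' @export
export_trees_graphml <- function(tr, anchors, atac, path) {
  if (!nrow(tr$edges)) {
    g <- igraph::make_empty_graph()
  } else {
    vdf <- unique(tr$nodes[, c("node_name", "kind")])
    lev <- tapply(tr$nodes$level, tr$nodes$node_name, min)
    vdf$level <- as.integer(lev[vdf$node_name])
    av <- atac[match(vdf$node_name, atac$node_name),
               grep("^atac_", names(atac)), drop = FALSE]
    vdf <- cbind(vdf, av)
    g <- igraph::graph_from_data_frame(
      tr$edges[, c("n1", "n2", "pet", "tree_id", "level")],
      directed = FALSE, vertices = vdf)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
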