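#' Assemble a reproducible end-to-end run configuration
#'
#' Bundles the three input paths, every stage's tunables and one global
#' seed; all stage seeds are derived deterministically from the global
#' seed by named substreams, so adding a stage never perturbs another
#' stage's randomness.
#'
#' @param associations path to the association edge TSV.
#' @param fasta path to the piRNA FASTA.
#' @param tree_numbers path to the disease tree-number TSV.
#' @param out_dir output directory for artifacts.
#' @param seed global integer seed.
#' @param min_degree piRNA degree filter threshold (default 2, i.e.
#'   degree-1 piRNAs are removed).
#' @param has_header whether the association TSV has a header row.
#' @param ratio negatives per positive.
#' @param k_folds cross-validation folds.
#' @param epochs,learning_rate,dropout,loss_weight,h1,h2,d0 model
#'   hyper-parameters (see [model_config()]).
#' @param mode_flags ablation/config switches (see
#'   [run_cross_validation()]).
#' @return a `run_config` list.
#' @export
run_config <- function(associations, fasta, tree_numbers, out_dir,
                       seed, min_degree = 2L, has_header = FALSE,
                       ratio = 1, k_folds = 5L, epochs = 12000L,
                       learning_rate = 0.002, dropout = 0.2,
                       loss_weight = 0.1, h1 = 64L, h2 = 64L, d0 = 64L,
                       mode_flags = list()) {
  if (missing(seed)) stop("a seed is mandatory")
  structure(
    list(associations = associations, fasta = fasta,
         tree_numbers = tree_numbers, out_dir = out_dir,
         seed = as.integer(seed), min_degree = as.integer(min_degree),
         has_header = has_header, ratio = ratio,
         k_folds = as.integer(k_folds), epochs = as.integer(epochs),
         learning_rate = learning_rate, dropout = dropout,
         loss_weight = loss_weight, h1 = as.integer(h1),
         h2 = as.integer(h2), d0 = as.integer(d0),
         mode_flags = mode_flags),
    class = "run_config"
  )
}

#' Cross-validate the model on the planted-structure benchmark
#'
#' One evaluation run of the standard synthetic benchmark: generate the
#' fixture, compute the sequence and semantic similarities, sample
#' negatives, build the 5-fold plan and run the per-fold pipeline. With
#' `permute_labels = TRUE` the positive/negative labels are shuffled over
#' the pooled pairs before splitting, which destroys the pair-label
#' association while keeping graph size, degree structure and class
#' balance: the resulting AUC distribution is the null reference.
#'
#' @param seed integer seed for this run (fixture, sampling and training
#'   seeds are derived from it).
#' @param mode_flags ablation switches (see [run_cross_validation()]).
#' @param ratio negatives per positive.
#' @param permute_labels run the label-permuted null instead.
#' @param epochs training epochs per fold (500 keeps a benchmark run in
#'   the tens of seconds).
#' @param k_folds folds, default 5.
#' @param spec fixture specification; defaults to the standard
#'   [fixture_spec()] benchmark.
#' @return the mean-row metrics (data frame with one row) with the full
#'   `eval_report` attached as attribute `"report"`.
#' @export
planted_benchmark <- function(seed, mode_flags = list(), ratio = 1,
                              permute_labels = FALSE, epochs = 500L,
                              k_folds = 5L,
                              spec = fixture_spec(seed = seed)) {
  fx <- generate_fixture(spec)
  assoc <- fx$assoc
  S_J <- jaccard_similarity(kmer_profile(fx$sequences[assoc$piRNA_ids]))
  dag <- build_disease_dag(tree_numbers = fx$tree_numbers)
  S_sem <- semantic_similarity_matrix(dag, assoc$disease_ids)
  pos <- assoc$edges
  neg <- sample_negatives(assoc, ratio, derive_seed(seed, "negatives"))
  if (permute_labels) {
    all_pairs <- rbind(pos, neg)
    lab <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
    lab <- with_seed(derive_seed(seed, "permute"), sample(lab))
    pos <- all_pairs[lab == 1, , drop = FALSE]
    neg <- all_pairs[lab == 0, , drop = FALSE]
  }
  splits <- make_cv_splits(pos, neg, k_folds, derive_seed(seed, "splits"))
  cfg <- model_config(epochs = epochs, seed = derive_seed(seed, "model"))
  report <- run_cross_validation(assoc, config = cfg, splits = splits,
                                 mode_flags = mode_flags,
                                 S_J = S_J, S_sem = S_sem)
  out <- report$table[nrow(report$table), ]
  attr(out, "report") <- report
  out
}

#' Run the full pipeline: load, filter, evaluate, report
#'
#' Load and degree-filter the associations, read sequences and the
#' disease hierarchy, sample negatives, build the cross-validation plan,
#' run the per-fold pipeline, and serialize the report, configuration and
#' last-fold link embeddings into the output directory.
#'
#' @param config a [run_config()].
#' @return the `eval_report`, invisibly; artifacts on disk under
#'   `config$out_dir` (`report.tsv`, `config.yaml`,
#'   `link_embeddings.tsv`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  assoc <- load_associations(config$associations, config$has_header)
  if (config$min_degree > 1L) {
    assoc <- filter_low_degree(assoc, config$min_degree, "piRNA")
  }
  sequences <- read_fasta(config$fasta)
  missing_seq <- setdiff(assoc$piRNA_ids, names(sequences))
  if (length(missing_seq)) {
    stop("no sequence for piRNA id(s): ",
         paste(utils::head(missing_seq, 5), collapse = ", "))
  }
  dag <- build_disease_dag(tree_numbers = config$tree_numbers)
  negatives <- sample_negatives(assoc, config$ratio,
                                derive_seed(config$seed, "negatives"))
  splits <- make_cv_splits(assoc$edges, negatives, config$k_folds,
                           derive_seed(config$seed, "splits"))
  mdl_cfg <- model_config(h1 = config$h1, h2 = config$h2,
                          dropout = config$dropout,
                          learning_rate = config$learning_rate,
                          epochs = config$epochs,
                          loss_weight = config$loss_weight,
                          seed = derive_seed(config$seed, "model"))
  flags <- config$mode_flags
  flags$d0 <- flags$d0 %||% config$d0
  report <- run_cross_validation(assoc, sequences, dag, mdl_cfg, splits,
                                 flags, keep_models = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report$table
  tab$fold <- ifelse(is.na(tab$fold), "mean", as.character(tab$fold))
  utils::write.table(format(tab, digits = 6),
                     file.path(config$out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    c(unclass(config)[setdiff(names(config), "mode_flags")],
      list(mode_flags = flags)),
    file.path(config$out_dir, "config.yaml"))
  last <- report$folds[[length(report$folds)]]
  export_link_embeddings(last$model, last$test_pairs, last$test_labels,
                         file.path(config$out_dir, "link_embeddings.tsv"),
                         assoc$piRNA_ids, assoc$disease_ids)
  invisible(report)
}
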