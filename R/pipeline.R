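# End-to-end orchestration: identity matrices -> markers -> tree ->
# delineation -> chemotaxonomy, from a single config, with a log
# sufficient to reproduce every number (parameters, seeds, config hash).

# FNV-1a 32-bit hash of a string (config fingerprinting)
fnv1a <- function(x) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(x)) {
    # xor on the low byte only (b < 256), keeping h a plain double
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply in two 16-bit halves to avoid precision loss
    h0 <- h %% 65536; h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  # h may exceed .Machine$integer.max; format the 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read a pipeline config
#'
#' YAML (if the 'yaml' package is installed) or JSON. See
#' [pipeline_config()] for the recognized fields.
#'
#' @param path config file.
#' @return config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Assemble a pipeline config
#'
#' @param genomes named character vector of genome FASTA paths (optional).
#' @param proteomes named character vector of proteome FASTA paths
#'   (optional).
#' @param profiles chemotaxonomic profile TSV path (optional).
#' @param focal focal strain id for delineation calls.
#' @param reference reference strain id for profile correlations.
#' @param required_tags marker-selection tags.
#' @param model distance model for the marker tree.
#' @param method tree method (`nj`, `upgma`, `me`).
#' @param bootstrap bootstrap replicates (0 = none).
#' @param seed global seed.
#' @param simulate optional list of arguments for the built-in synthetic
#'   demo (see [simulate_pipeline_inputs()]); when present, file inputs
#'   are generated instead of read.
#' @param out_dir output directory.
#' @return validated config list.
#' @export
pipeline_config <- function(genomes = NULL, proteomes = NULL,
                            profiles = NULL, focal = NULL, reference = NULL,
                            required_tags = character(), model = "p",
                            method = "nj", bootstrap = 0L, seed = 1L,
                            simulate = NULL, out_dir = tempfile("pipeline")) {
  cfg <- list(genomes = genomes, proteomes = proteomes, profiles = profiles,
              focal = focal, reference = reference,
              required_tags = required_tags, model = model, method = method,
              bootstrap = bootstrap, seed = seed, simulate = simulate,
              out_dir = out_dir)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  for (f in c(cfg$genomes, cfg$proteomes, cfg$profiles))
    if (!is.null(f) && !file.exists(f))
      stop("config validation: missing input file: ", f)
  stopifnot(cfg$method %in% c("nj", "upgma", "me"),
            cfg$model %in% c("p", "poisson", "jtt", "dayhoff", "kimura-nt"))
  invisible(cfg)
}

#' Generate the synthetic demo inputs for the pipeline
#'
#' Two three-strain genera plus one planted outlier strain: proteomes are
#' simulated on a tree whose within-genus distances are short and whose
#' outlier branch is long, and small genomes are evolved from per-genus
#' ancestors, so that identity statistics, marker selection, the tree and
#' the delineation calls all have known expected outcomes.
#'
#' @param seed global seed.
#' @param genome_length genome size in bp (small by default: the demo
#'   exercises the machinery, not its scaling).
#' @param n_families number of simulated marker families.
#' @return list with `genomes`, `proteomes`, `outlier`, `truth`, `tree`.
#' @export
simulate_pipeline_inputs <- function(seed = 1L, genome_length = 20000L,
                                     n_families = 5L) {
  strains <- c("gA_1", "gA_2", "gA_3", "gB_1", "gB_2", "gB_3", "outlier")
  tre <- ape::read.tree(text = paste0(
    "(((gA_1:0.02,gA_2:0.02):0.01,gA_3:0.03):0.25,",
    "((gB_1:0.02,gB_2:0.02):0.01,gB_3:0.03):0.25,outlier:0.45);"))
  tags <- stats::setNames(rep(list("shikimate"), n_families),
                          sprintf("aro%02d", seq_len(n_families)))
  fams <- simulate_families(tree = tre, n_families = n_families,
                            lengths = 250L, tags = tags,
                            seed = child_seed(seed, "pipeline-proteomes"))
  # genomes: evolve each strain from a shared root at a strain rate
  rate <- c(gA_1 = 0.02, gA_2 = 0.02, gA_3 = 0.025,
            gB_1 = 0.02, gB_2 = 0.02, gB_3 = 0.025, outlier = 0.09)
  root <- evolve_genome(evolve_spec(root_length = genome_length,
                                    substitution_rate = 0,
                                    seed = child_seed(seed, "pipeline-root")))
  genomes <- lapply(strains, function(s) {
    g <- evolve_genome(evolve_spec(root_length = genome_length,
                                   substitution_rate = rate[[s]],
                                   seed = child_seed(seed, paste0("g-", s))),
                       root = root$ancestor)$derived
    g$id <- s
    g
  })
  names(genomes) <- strains
  list(genomes = genomes, proteomes = fams$proteomes, outlier = "outlier",
       truth = fams$truth, tree = tre)
}

#' Run the full pipeline
#'
#' Stages run in dependency order; every output file carries the config
#' hash in the log. A rerun with the same config and seed is
#' reproducible.
#'
#' @param config a [pipeline_config()] list or a path to a YAML/JSON
#'   config file.
#' @return list with the computed objects (`ani`, `aai`, `tree`,
#'   `species`, `genus`, `correlations`, `out_dir`, `log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, null = "null")
  hash <- fnv1a(as.character(cfg_json))
  log <- c(sprintf("config_hash\t%s", hash),
           sprintf("seed\t%d", as.integer(config$seed)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # --- inputs ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", do.call(simulate_pipeline_inputs,
                                     c(list(seed = config$seed),
                                       config$simulate)))
    genomes <- sim$genomes
    proteomes <- sim$proteomes
    if (is.null(config$focal)) config$focal <- sim$outlier
  } else {
    genomes <- if (!is.null(config$genomes))
      stage("read-genomes", Map(function(p, n) read_fasta(p, "genome", id = n),
                                config$genomes, names(config$genomes)))
    proteomes <- if (!is.null(config$proteomes))
      stage("read-proteomes",
            Map(function(p, n) read_fasta(p, "proteins", id = n),
                config$proteomes, names(config$proteomes)))
  }
  out <- list(out_dir = config$out_dir)
  # --- identity -------------------------------------------------------
  if (!is.null(genomes)) {
    out$ani <- stage("ani", build_matrix(genomes, function(a, b)
      fragment_ani(a, b)$ani, kind = "ANI"))
    write_matrix_tsv(out$ani, file.path(config$out_dir, "ani.tsv"))
    log <- c(log, sprintf("ani\tstrains=%d", length(genomes)))
  }
  if (!is.null(proteomes)) {
    out$aai <- stage("aai", build_matrix(proteomes, function(a, b)
      rbh_aai(a, b)$aai, kind = "AAI", symmetric = TRUE))
    write_matrix_tsv(out$aai, file.path(config$out_dir, "aai.tsv"))
    log <- c(log, sprintf("aai\tstrains=%d", length(proteomes)))
  }
  # --- markers + tree -------------------------------------------------
  if (!is.null(proteomes) && length(proteomes) >= 3L) {
    tab <- stage("orthologs", cluster_orthologs(proteomes))
    sel <- stage("markers", select_markers(tab,
                                           required_tags = config$required_tags))
    log <- c(log, sprintf("markers\tselected=%s", paste(sel, collapse = ",")))
    alns <- stage("align", lapply(sel, function(f) {
      mem <- tab$families[[f]]
      seqs <- stats::setNames(
        vapply(seq_len(nrow(mem)), function(k)
          proteomes[[mem$strain[k]]]$proteins[[mem$protein[k]]],
          character(1)),
        mem$strain)
      progressive_align(seqs)
    }))
    names(alns) <- sel
    conc <- stage("concatenate", concatenate_markers(alns))
    out$concatenated <- conc
    out$tree <- stage("tree", {
      if (config$bootstrap > 0) {
        bootstrap_support(conc$alignment, model = config$model,
                          builder = config$method,
                          replicates = config$bootstrap,
                          seed = child_seed(config$seed, "bootstrap"))
      } else {
        d <- pairwise_distance(conc$alignment, config$model)
        switch(config$method, nj = neighbor_joining(d), upgma = upgma(d),
               me = minimum_evolution(d))
      }
    })
    write_newick(out$tree, file.path(config$out_dir, "markers.nwk"))
    log <- c(log, sprintf("tree\tmodel=%s method=%s bootstrap=%d",
                          config$model, config$method, config$bootstrap))
  }
  # --- delineation ----------------------------------------------------
  if (!is.null(config$focal)) {
    calls <- list()
    if (!is.null(out$ani))
      calls$species <- stage("species-call",
                             species_call(config$focal, out$ani))
    if (!is.null(out$aai) && !is.null(out$tree))
      calls$genus <- stage("genus-call",
                           genus_call(config$focal, out$aai, out$tree))
    out <- c(out, calls)
    rows <- lapply(calls, function(cl)
      data.frame(strain = cl$strain, verdict = cl$verdict,
                 evidence = paste(cl$evidence, collapse = "; ")))
    utils::write.table(do.call(rbind, rows),
                       file.path(config$out_dir, "taxon_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- c(log, vapply(calls, function(cl)
      sprintf("call\t%s\t%s", cl$strain, cl$verdict), character(1)))
  }
  # --- chemotaxonomy --------------------------------------------------
  if (!is.null(config$profiles)) {
    prof <- stage("profiles", read_profile_tsv(config$profiles))
    ref <- config$reference %||% names(prof)[1L]
    cors <- vapply(names(prof), function(s)
      profile_correlation(prof[[ref]], prof[[s]]), numeric(1))
    out$correlations <- data.frame(strain = names(prof), r = unname(cors))
    utils::write.table(out$correlations,
                       file.path(config$out_dir, "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <- c(log, sprintf("chemotax\treference=%s", ref))
  }
  writeLines(log, file.path(config$out_dir, "pipeline.log"))
  out$log <- log
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a combined lower/upper identity table
#'
#' One table with ANI below the diagonal and AAI above, integer-rounded
#' half-up as printed tables do, with an attribute marking within-cluster
#' cells ("boxes").
#'
#' @param m_ani,m_aai [similarity_matrix()] objects on the same labels.
#' @param clusters optional list of label vectors (e.g. from
#'   [threshold_clusters()]).
#' @return integer matrix with attribute `box` (logical matrix).
#' @export
report_table1 <- function(m_ani, m_aai, clusters = NULL) {
  if (!identical(m_ani$labels, m_aai$labels))
    stop("label mismatch between ANI and AAI matrices")
  lab <- m_ani$labels
  n <- length(lab)
  half_up <- function(x) floor(x + 0.5)
  out <- matrix(100L, n, n, dimnames = list(lab, lab))
  low <- row(out) > col(out); up <- row(out) < col(out)
  out[low] <- as.integer(half_up(m_ani$values[low]))
  out[up] <- as.integer(half_up(m_aai$values[up]))
  box <- matrix(FALSE, n, n, dimnames = list(lab, lab))
  for (cl in clusters) if (length(cl) > 1L) {
    idx <- match(cl, lab)
    box[idx, idx] <- TRUE
  }
  diag(box) <- FALSE
  attr(out, "box") <- box
  out
}
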