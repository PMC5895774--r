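# Seeded synthetic cohort generator.  Full 10-steroid panels per class are
# drawn from log-normal marginals with an exchangeable log-scale
# correlation, then distorted by class-specific enzyme perturbations on the
# pathway graph (products of the enzyme's reactions scaled down or up, the
# accumulating substrate side scaled the opposite way), and paired with a
# class-specific log-normal PSA.  Defaults emulate the clinical picture the
# analysis assumes: DHEAS and cortisol one to three orders of magnitude
# above the remaining steroids, most steroids (androgens in particular)
# lower in the cancer class, PSA separating HC from the two prostate
# classes, and class sizes 20 PCa / 20 BPH / 31 HC.

.BASE_MEDIANS <- c(
  "aldosterone" = 0.10, "corticosterone" = 3.0, "cortisol" = 100,
  "11-deoxycortisol" = 0.40, "androstenedione" = 1.2, "testosterone" = 4.5,
  "DHEA" = 3.0, "DHEAS" = 1200, "17-OH-progesterone" = 1.0,
  "progesterone" = 0.15
)

.CLASS_MULTIPLIERS <- list(
  HC  = stats::setNames(rep(1, 10), names(.BASE_MEDIANS)),
  BPH = c("aldosterone" = 1.0, "corticosterone" = 0.9, "cortisol" = 1.15,
          "11-deoxycortisol" = 1.1, "androstenedione" = 0.8,
          "testosterone" = 0.7, "DHEA" = 0.85, "DHEAS" = 1.05,
          "17-OH-progesterone" = 0.9, "progesterone" = 0.8),
  PCa = c("aldosterone" = 0.9, "corticosterone" = 1.1, "cortisol" = 0.85,
          "11-deoxycortisol" = 0.8, "androstenedione" = 0.5,
          "testosterone" = 0.45, "DHEA" = 0.5, "DHEAS" = 0.45,
          "17-OH-progesterone" = 0.7, "progesterone" = 1.3)
)

.PSA_PARAMS <- list(
  HC  = c(meanlog = log(1.0), sdlog = 0.55),
  BPH = c(meanlog = log(6.3), sdlog = 0.45),
  PCa = c(meanlog = log(9.5), sdlog = 0.90)
)

#' Synthetic cohort generator configuration
#'
#' Holds the per-class distributional assumptions of the generator.  The
#' defaults are the package's declared study conditions: log-normal
#' marginals whose HC medians put DHEAS and cortisol far above the other
#' eight steroids, cancer-class multipliers lowering most steroids
#' (androgens most strongly), a mild benign-hypertrophy pattern, an
#' exchangeable log-scale correlation, class-specific enzyme perturbations
#' (a partial P450C17 deficit in the cancer class, a mild 17b-HSD deficit
#' in the benign class), and PSA distributions bracketing the clinical
#' ranges (HC mostly below 2.5 ng/mL).
#'
#' @param seed Mandatory integer seed; all draws derive from it.
#' @param class_sizes Named integer vector of subjects per class.
#' @param base_medians HC median concentration per analyte (ng/mL).
#' @param class_multipliers Named list (per class) of median multipliers.
#' @param log_sd Log-scale standard deviation shared by all analytes.
#' @param log_cor Exchangeable log-scale correlation between analytes
#'   (must keep the covariance positive definite).
#' @param enzyme_perturbations Named list (per class) of
#'   `enzyme label -> factor` applied via [perturb_enzyme()].
#' @param psa_params Named list (per class) of `c(meanlog, sdlog)` for the
#'   log-normal PSA draw.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             class_sizes = c(PCa = 20, BPH = 20, HC = 31),
                             base_medians = .BASE_MEDIANS,
                             class_multipliers = .CLASS_MULTIPLIERS,
                             log_sd = 0.35,
                             log_cor = 0.2,
                             enzyme_perturbations = list(
                               PCa = c("P450C17" = 0.8),
                               BPH = c("17b-HSD" = 0.9),
                               HC = NULL),
                             psa_params = .PSA_PARAMS) {
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for the generator", call. = FALSE)
  stopifnot(all(class_sizes >= 0), !is.null(names(class_sizes)))
  stopifnot(setequal(names(base_medians), .ANALYTES))
  if (log_sd <= 0) stop("log_sd must be positive", call. = FALSE)
  n <- length(base_medians)
  if (log_cor < -1 / (n - 1) || log_cor >= 1)
    stop("log_cor leaves the positive-definite range", call. = FALSE)
  structure(list(seed = as.integer(seed), class_sizes = class_sizes,
                 base_medians = base_medians[.ANALYTES],
                 class_multipliers = class_multipliers,
                 log_sd = log_sd, log_cor = log_cor,
                 enzyme_perturbations = enzyme_perturbations,
                 psa_params = psa_params),
            class = "generator_config")
}

#' Apply an enzyme perturbation to a panel
#'
#' A mass-action caricature of an enzymatic deficit or excess: every
#' steroid downstream of the enzyme's reactions (the products and their
#' descendants) is multiplied by `factor`, while the accumulating
#' substrate side (the immediate substrates and what remains reachable
#' from them once the enzyme's own reactions are removed) is divided by
#' `factor`.  Steroids on both sides, or on neither, are left unchanged;
#' graph nodes absent from the panel are ignored.
#'
#' @param panel A [steroid_panel()].
#' @param graph Pathway graph from [steroidogenesis_graph()].
#' @param enzyme Enzyme label present in the graph's edge attributes.
#' @param factor Positive multiplier; `factor = 1` is the identity, values
#'   below 1 model a deficit.
#' @return The perturbed panel.
#' @export
#' @examples
#' p <- steroid_panel(setNames(c(0.1, 3, 100, 0.4, 1.2, 4.5, 3, 1200, 1, 0.15),
#'                             steroid_analytes()))
#' perturb_enzyme(p, enzyme = "21-hydroxylase", factor = 0.5)
perturb_enzyme <- function(panel, graph = steroidogenesis_graph(), enzyme,
                           factor) {
  panel <- steroid_panel(panel)
  stopifnot(length(factor) == 1, factor > 0)
  eidx <- which(igraph::edge_attr(graph, "enzyme") == enzyme)
  if (length(eidx) == 0)
    stop("unknown enzyme: ", enzyme, call. = FALSE)
  ends <- igraph::ends(graph, igraph::E(graph)[eidx])
  tails <- unique(ends[, 1]); heads <- unique(ends[, 2])
  down <- unique(unlist(lapply(heads, function(h)
    names(igraph::subcomponent(graph, h, mode = "out")))))
  g_cut <- igraph::delete_edges(graph, igraph::E(graph)[eidx])
  up <- unique(unlist(lapply(tails, function(t)
    names(igraph::subcomponent(g_cut, t, mode = "out")))))
  both <- intersect(down, up)
  down <- setdiff(down, both); up <- setdiff(up, both)
  out <- panel
  d <- intersect(down, names(out)); u <- intersect(up, names(out))
  out[d] <- out[d] * factor
  out[u] <- out[u] / factor
  out
}

# Deterministic per-class sub-seed, kept under 2^31.
.sub_seed <- function(seed, index) {
  (as.double(seed) * 48271 + index * 9973) %% 2147483647
}

#' Simulate a labeled steroid cohort
#'
#' Draws, class by class, correlated log-normal 10-steroid panels, applies
#' the class's enzyme perturbations, and draws PSA; the result is a
#' [steroid_cohort()] with panel columns, `psa`, a `dheas` convenience
#' copy, and ids of the form `SIM-<class><number>`.  All randomness
#' derives from the config seed (per-class substreams are derived
#' deterministically), so equal configs give byte-identical cohorts.
#'
#' @param config A [generator_config()].
#' @param graph Pathway graph used for the enzyme perturbations.
#' @return A [steroid_cohort()] with `sum(class_sizes)` rows.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(seed = 1))
#' table(cohort$class)
simulate_cohort <- function(config, graph = steroidogenesis_graph()) {
  stopifnot(inherits(config, "generator_config"))
  n_a <- length(config$base_medians)
  sigma <- config$log_sd^2 *
    ((1 - config$log_cor) * diag(n_a) + config$log_cor)
  rows <- list()
  for (ci in seq_along(config$class_sizes)) {
    cls <- names(config$class_sizes)[ci]
    n <- config$class_sizes[[ci]]
    if (n == 0) next
    set.seed(.sub_seed(config$seed, ci))
    mult <- config$class_multipliers[[cls]][.ANALYTES]
    mu <- log(config$base_medians * mult)
    draws <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
    if (n == 1) draws <- matrix(draws, nrow = 1)
    colnames(draws) <- .ANALYTES
    pp <- config$psa_params[[cls]]
    psa <- stats::rlnorm(n, meanlog = pp[["meanlog"]], sdlog = pp[["sdlog"]])
    pert <- config$enzyme_perturbations[[cls]]
    for (s in seq_len(n)) {
      panel <- steroid_panel(exp(draws[s, ]))
      for (enz in names(pert))
        panel <- perturb_enzyme(panel, graph, enz, pert[[enz]])
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("SIM-%s%03d", cls, s), class = cls,
        psa = psa[s], dheas = panel[["DHEAS"]],
        as.list(panel), check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  steroid_cohort(do.call(rbind, rows),
                 provenance = sprintf("simulate_cohort(seed = %d)", config$seed))
}
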