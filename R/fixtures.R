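# Synthetic labelled SMILES fixtures.
#
# Small ring/chain cores carry substitution sites that are decorated with
# functional-group fragments drawn from the default knowledge table, so
# fixture tasks are learnable exactly through the features the model is
# built to exploit.  Classification labels are structural indicators
# (presence of a target group, established with the same substructure
# matcher used for augmentation, so implied-group chemistry such as a
# carboxyl containing a hydroxyl is labelled consistently); regression
# targets are additive per-group scores plus Gaussian noise.

.fixture_scaffolds <- c(
  "c1cc({1})cc({2})c1",    # benzene
  "C1CC({1})CC({2})C1",    # cyclohexane
  "c1cc({1})ncc1{2}",      # pyridine
  "c1cc({1})oc1{2}",       # furan
  "c1cc({1})sc1",          # thiophene
  "CCC({1})CC{2}",         # pentane chain
  "CC({1})C({2})C",        # branched butane
  "C1CC({1})CC1{2}",       # cyclopentane
  "C1CC({1})OC1",          # tetrahydrofuran
  "C1CC({1})NCC1")         # piperidine

.fixture_decorations <- c(
  hydroxyl = "O", amino = "N", methyl = "C", carboxyl = "C(=O)O",
  nitro = "[N+](=O)[O-]", halogen = "Cl", thiol = "S", ether = "OC",
  amide = "C(=O)N", acetyl = "C(C)=O")

# additive contribution of each decoration to the regression score
.fixture_weights <- c(
  hydroxyl = -1.2, amino = -0.8, methyl = 0.5, carboxyl = -1.5,
  nitro = 0.9, halogen = 0.7, thiol = 0.3, ether = -0.4,
  amide = -1.0, acetyl = -0.2)

#' Specify a synthetic fixture dataset
#'
#' @param n_molecules Number of distinct molecules to generate.
#' @param label_rule Either the name of a functional group (classification:
#'   label 1 iff the group occurs in the molecule) or `"additive"`
#'   (regression: sum of per-decoration weights + Gaussian noise).
#' @param sigma Noise standard deviation for the additive rule (default
#'   0.25; 0 gives exact additive scores).
#' @param scaffolds Character vector of core templates with `({k})` /
#'   `{k}` substitution sites.
#' @param decorations Named character vector of attachable fragments.
#' @param weights Named numeric additive weights (regression).
#' @param decoration_prob Probability that a site is decorated.
#' @param class_balance Target positive fraction for classification
#'   (default 0.5, met by quota sampling).
#' @param seed Integer seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 200L, label_rule = "hydroxyl",
                         sigma = 0.25, scaffolds = .fixture_scaffolds,
                         decorations = .fixture_decorations,
                         weights = .fixture_weights,
                         decoration_prob = 0.7, class_balance = 0.5,
                         seed = 1L) {
  task_type <- if (identical(label_rule, "additive")) "regression"
               else "classification"
  structure(list(n_molecules = as.integer(n_molecules),
                 label_rule = label_rule, sigma = sigma,
                 scaffolds = scaffolds, decorations = decorations,
                 weights = weights, decoration_prob = decoration_prob,
                 class_balance = class_balance, task_type = task_type,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.instantiate <- function(template, frags) {
  out <- template
  for (k in seq_len(3L)) {
    frag <- if (k <= length(frags)) frags[k] else ""
    out <- if (nzchar(frag)) {
      sub(sprintf("\\{%d\\}", k), frag, out)
    } else {
      # drop the whole "({k})" branch first, then any bare "{k}" site
      sub(sprintf("\\{%d\\}", k), "",
          sub(sprintf("\\(\\{%d\\}\\)", k), "", out))
    }
  }
  out
}

.n_sites <- function(template)
  sum(vapply(1:3, function(k) grepl(sprintf("\\{%d\\}", k), template),
             logical(1)))

#' Generate a synthetic fixture dataset
#'
#' Samples scaffold/decoration combinations under the spec's seed, keeping
#' distinct molecules only.  Classification labels come from substructure
#' matching of the target group (quota sampling keeps the class balance near
#' the target); regression targets are the additive decoration score plus
#' `N(0, sigma^2)` noise.  Every generated molecule parses.
#'
#' @param spec A `fixture_spec`.
#' @return A `property_dataset` with one task named after the label rule.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  kb <- build_knowledge_base()
  classify <- spec$task_type == "classification"
  if (classify && !spec$label_rule %in% names(kb$functional_groups))
    stop("label_rule '", spec$label_rule, "' is not a known functional group")
  n <- spec$n_molecules
  want_pos <- round(n * spec$class_balance)
  want_neg <- n - want_pos
  seen <- new.env(parent = emptyenv())
  smiles <- character(0); labels <- numeric(0)
  n_pos <- 0L; n_neg <- 0L
  attempts <- 0L; max_attempts <- 500L * n
  while (length(smiles) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    template <- sample(spec$scaffolds, 1L)
    ns <- .n_sites(template)
    frags <- character(ns)
    deco_names <- character(0)
    for (k in seq_len(ns)) {
      if (stats::runif(1) < spec$decoration_prob) {
        d <- sample(names(spec$decorations), 1L)
        frags[k] <- spec$decorations[[d]]
        deco_names <- c(deco_names, d)
      }
    }
    smi <- .instantiate(template, frags)
    if (!is.null(seen[[smi]])) next
    g <- tryCatch(parse_smiles(smi, add_hydrogens = TRUE),
                  error = function(e) NULL)
    if (is.null(g)) next   # defensive: templates are constructed to parse
    if (classify) {
      m <- match_functional_groups(g, kb)
      lab <- as.numeric(any(vapply(m, function(x)
        x$group == spec$label_rule, logical(1))))
      if (lab == 1 && n_pos >= want_pos) next
      if (lab == 0 && n_neg >= want_neg) next
      if (lab == 1) n_pos <- n_pos + 1L else n_neg <- n_neg + 1L
    } else {
      w <- spec$weights[deco_names]
      lab <- sum(w, na.rm = TRUE) + stats::rnorm(1, sd = spec$sigma)
    }
    seen[[smi]] <- TRUE
    smiles <- c(smiles, smi)
    labels <- c(labels, lab)
  }
  if (length(smiles) < n)
    stop("fixture spec yields only ", length(smiles),
         " distinct molecule(s); requested ", n)
  task <- if (classify) spec$label_rule else "score"
  property_dataset(smiles, matrix(labels, ncol = 1,
                                  dimnames = list(NULL, task)),
                   task, spec$task_type, validate = FALSE)
}
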