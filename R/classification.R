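#' Leave-one-subject-out one-vs-one linear SVM accuracy
#'
#' Cross-participant three-way decoding of condition patterns. For each
#' cross-validation fold one subject's three samples are held out; three
#' binary linear SVMs (pain vs touch, pain vs control, touch vs control)
#' are trained on all remaining subjects' samples and the held-out samples
#' are labelled by majority vote, ties broken deterministically in the
#' fixed label order pain < touch < control. The regularisation parameter
#' follows the norm-adaptive heuristic `C = 1 / mean(||x||^2)` over the
#' training samples (`costHeuristic = "squared-norm"`, the default;
#' `"norm"` divides by the mean norm instead), emulating auto-scaled
#' regularisation of the reference LIBSVM front end; an explicit `cost`
#' overrides the heuristic.
#'
#' @param samples numeric matrix, one row per sample (subject x condition),
#'   one column per feature (sphere voxel).
#' @param labels condition of each sample (`pain`/`touch`/`control`).
#' @param groups subject id of each sample.
#' @param cost explicit SVM cost; `NULL` (default) uses the heuristic.
#' @param costHeuristic `"squared-norm"` or `"norm"`.
#' @return overall accuracy in [0, 1]: total correct predictions divided by
#'   `nSubjects * 3`.
#' @examples
#' p <- rbind(diag(3), diag(3)) # 2 subjects, orthogonal patterns
#' losoAccuracy(p, rep(c("pain", "touch", "control"), 2),
#'              rep(c("a", "b"), each = 3))
#' @export
losoAccuracy <- function(samples, labels, groups, cost = NULL,
                         costHeuristic = c("squared-norm", "norm")) {
    costHeuristic <- match.arg(costHeuristic)
    samples <- as.matrix(samples)
    if (ncol(samples) < 1L)
        stop("undefined sphere: empty pattern vectors")
    labels <- factor(as.character(labels), levels = .CONDITIONS)
    if (anyNA(labels)) stop("labels must be pain/touch/control")
    groups <- as.character(groups)
    subjects <- unique(groups)
    if (length(subjects) < 2L)
        stop("dataset error: at least 2 subjects are required")
    pairs <- list(c("pain", "touch"), c("pain", "control"),
                  c("touch", "control"))
    nCorrect <- 0L
    nTotal <- 0L
    for (s in subjects) {
        test <- groups == s
        train <- !test
        Xtr <- samples[train, , drop = FALSE]
        Xte <- samples[test, , drop = FALSE]
        C <- if (!is.null(cost)) cost else {
            nrm2 <- rowSums(Xtr^2)
            den <- if (costHeuristic == "squared-norm") mean(nrm2)
                   else mean(sqrt(nrm2))
            if (den <= 0) 1 else 1 / den
        }
        votes <- matrix(0L, nrow = nrow(Xte), ncol = 3L,
                        dimnames = list(NULL, .CONDITIONS))
        for (pr in pairs) {
            sel <- labels[train] %in% pr
            y <- factor(as.character(labels[train][sel]), levels = pr)
            fit <- e1071::svm(Xtr[sel, , drop = FALSE], y,
                              type = "C-classification",
                              kernel = "linear", cost = C, scale = FALSE)
            pred <- as.character(predict(fit, Xte))
            for (k in seq_along(pred))
                votes[k, pred[k]] <- votes[k, pred[k]] + 1L
        }
        # majority vote; which.max takes the first maximum, i.e. ties break
        # in the fixed order pain < touch < control
        predLab <- .CONDITIONS[apply(votes, 1L, which.max)]
        nCorrect <- nCorrect + sum(predLab == as.character(labels[test]))
        nTotal <- nTotal + length(predLab)
    }
    nCorrect / nTotal
}

#' Cross-participant classification searchlight
#'
#' Runs [losoAccuracy()] inside every searchlight sphere of a complete
#' subject-by-condition cohort, producing a voxelwise map of
#' across-participant classification accuracies (the per-voxel denominator
#' is `nSubjects * 3`).
#'
#' @param x a [ConditionMaps-class] with every subject contributing exactly
#'   one map per condition.
#' @param sphere a [SphereSpec-class] (default radius 3).
#' @param centers optional subset of mask-voxel indices (see
#'   [runSearchlight()]).
#' @inheritParams losoAccuracy
#' @return A [SearchlightResult-class] of accuracies in [0, 1].
#' @export
classificationSearchlight <- function(x, sphere = sphereOffsets(3),
                                      centers = NULL, cost = NULL,
                                      costHeuristic = c("squared-norm",
                                                        "norm")) {
    costHeuristic <- match.arg(costHeuristic)
    .checkCompleteCohort(x, minSubjects = 2L)
    cd <- colData(x)
    labels <- as.character(cd$condition)
    groups <- as.character(cd$subject)
    stat <- function(P) losoAccuracy(t(P), labels, groups, cost = cost,
                                     costHeuristic = costHeuristic)
    runSearchlight(x, stat, sphere = sphere, centers = centers,
                   statisticName = "loso_accuracy")
}
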