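#' Published fixed decision rule on omega1, age and phi1
#'
#' Encodes the published screening tree exactly as printed: a systolic
#' intrinsic frequency below 107.6 bpm indicates normal LVEF regardless of
#' age; above it, patients aged 6 or older are classified low, while for
#' those younger than 6 the intrinsic phase decides (low only when
#' `phi1 < -0.65` rad). Comparisons are encoded with the printed
#' strict/non-strict sides, so equality at a threshold falls to the
#' non-strict side.
#'
#' @param omega1_bpm Systolic intrinsic frequency in bpm (vectorized).
#' @param age Age in years.
#' @param phi1 Systolic intrinsic phase in rad.
#' @return Data frame with `label` (`"low"`/`"normal"`) and `rule`, the
#'   comparison path taken.
#' @export
classify_fixed_tree_A <- function(omega1_bpm, age, phi1) {
  n <- max(length(omega1_bpm), length(age), length(phi1))
  omega1_bpm <- rep_len(omega1_bpm, n)
  age <- rep_len(age, n)
  phi1 <- rep_len(phi1, n)
  label <- character(n); rule <- character(n)
  low_o <- omega1_bpm < 107.6
  label[low_o] <- "normal"
  rule[low_o] <- "omega1<107.6"
  older <- !low_o & age >= 6
  label[older] <- "low"
  rule[older] <- "omega1>=107.6 & age>=6"
  yp <- !low_o & age < 6 & phi1 < -0.65
  label[yp] <- "low"
  rule[yp] <- "omega1>=107.6 & age<6 & phi1<-0.65"
  yn <- !low_o & age < 6 & !(phi1 < -0.65)
  label[yn] <- "normal"
  rule[yn] <- "omega1>=107.6 & age<6 & phi1>=-0.65"
  data.frame(label = label, rule = rule, stringsAsFactors = FALSE)
}

#' Published fixed decision rule on omega1 and omegai1
#'
#' The age-universal screening rule: `omegai1 > 1.6` indicates low LVEF and
#' `omegai1 < 1.22` normal LVEF; in the intermediate band the call is made
#' by `omega1 > 107.6` bpm (low above). Equality at a threshold falls to the
#' non-strict side of the printed strict comparison.
#'
#' @param omega1_bpm Systolic intrinsic frequency in bpm (vectorized).
#' @param omegai1 Heart-rate-normalized index (unitless).
#' @return Data frame with `label` and `rule` as in
#'   [classify_fixed_tree_A()].
#' @export
classify_fixed_tree_B <- function(omega1_bpm, omegai1) {
  n <- max(length(omega1_bpm), length(omegai1))
  omega1_bpm <- rep_len(omega1_bpm, n)
  omegai1 <- rep_len(omegai1, n)
  label <- character(n); rule <- character(n)
  hi <- omegai1 > 1.6
  label[hi] <- "low"; rule[hi] <- "omegai1>1.6"
  lo <- !hi & omegai1 < 1.22
  label[lo] <- "normal"; rule[lo] <- "omegai1<=1.6 & omegai1<1.22"
  mid_hi <- !hi & !lo & omega1_bpm > 107.6
  label[mid_hi] <- "low"
  rule[mid_hi] <- "1.22<=omegai1<=1.6 & omega1>107.6"
  mid_lo <- !hi & !lo & !(omega1_bpm > 107.6)
  label[mid_lo] <- "normal"
  rule[mid_lo] <- "1.22<=omegai1<=1.6 & omega1<=107.6"
  data.frame(label = label, rule = rule, stringsAsFactors = FALSE)
}

# weighted Gini impurity contribution of a node: 2 * npos * nneg / n
gini_weight <- function(n_pos, n) {
  ifelse(n > 0, 2 * n_pos * (n - n_pos) / n, 0)
}

# Best split of one node over the given predictors.
# Returns NULL or list(feature, threshold, decrease, left_idx, right_idx).
best_split <- function(data, idx, predictors, label) {
  y <- label[idx]
  parent <- gini_weight(sum(y), length(y))
  if (parent <= 0) return(NULL)
  best <- NULL
  for (f in seq_along(predictors)) {
    x <- data[[predictors[f]]][idx]
    ox <- order(x)
    xs <- x[ox]; ys <- y[ox]
    distinct <- which(diff(xs) > 0)
    if (length(distinct) == 0L) next
    cum_pos <- cumsum(ys)
    nL <- distinct
    posL <- cum_pos[distinct]
    n <- length(ys); pos <- cum_pos[n]
    dec <- parent - gini_weight(posL, nL) - gini_weight(pos - posL, n - nL)
    k <- which.max(dec)   # first max -> smallest threshold on ties
    if (dec[k] > 1e-12 * n && (is.null(best) || dec[k] > best$decrease + 1e-12 * n)) {
      thr <- (xs[distinct[k]] + xs[distinct[k] + 1L]) / 2
      best <- list(feature = predictors[f], threshold = thr,
                   decrease = dec[k],
                   left_idx = idx[x < thr], right_idx = idx[x >= thr])
    }
  }
  best
}

#' Train a constrained CART classification tree
#'
#' Greedy binary CART with Gini impurity, honouring two structural
#' constraints: the total number of splits may not exceed
#' `1 + length(predictors)`, and a node may only be split when it holds
#' more than 10 training samples (i.e. at least 11). Growth is best-first:
#' among all currently splittable nodes the one whose best split most
#' reduces the weighted impurity is expanded, until the split budget or the
#' impurity floor is reached. Split thresholds sit at midpoints between
#' consecutive distinct sorted feature values. Ties are broken
#' deterministically: lower predictor index first, then smaller threshold,
#' then the earlier-created node.
#'
#' @param data Data frame containing the predictor columns and a logical
#'   (or 0/1) label column, `TRUE`/1 = positive = low LVEF.
#' @param predictors Character vector of predictor column names; their
#'   order fixes the tie-break priority.
#' @param label Name of the label column.
#' @param max_splits Split budget; defaults to `1 + length(predictors)`.
#' @param min_split_size Minimum node size allowing a split (default 11,
#'   the literal reading of "greater than 10").
#' @return Object of class `if_cart`: a data frame of nodes (`id`,
#'   `feature`, `threshold`, `left`, `right`, `n`, `n_pos`, `pos_frac`,
#'   `leaf`, `pred`) with attributes `predictors` and `constraints`.
#'   Routing is `<` to the left child, `>=` to the right.
#' @export
train_cart <- function(data, predictors, label = "label",
                       max_splits = NULL, min_split_size = 11L) {
  if (nrow(data) < 2L) abort_data("need at least 2 subjects to train")
  missing_cols <- setdiff(c(predictors, label), names(data))
  if (length(missing_cols))
    abort_data(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  y <- as.logical(data[[label]])
  if (anyNA(y)) abort_data("labels contain NA")
  max_splits <- max_splits %||% (1L + length(predictors))

  nodes <- list()
  new_node <- function(idx) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, idx = idx, feature = NA_character_,
                         threshold = NA_real_, left = NA_integer_,
                         right = NA_integer_, n = length(idx),
                         n_pos = sum(y[idx]), leaf = TRUE)
    id
  }
  new_node(seq_len(nrow(data)))
  splits_used <- 0L
  repeat {
    if (splits_used >= max_splits) break
    # best candidate over all splittable leaves, earlier node wins ties
    cand_id <- NA_integer_; cand <- NULL
    for (nd in nodes) {
      if (!nd$leaf || nd$n < min_split_size) next
      sp <- best_split(data, nd$idx, predictors, y)
      if (is.null(sp)) next
      if (is.null(cand) || sp$decrease > cand$decrease + 1e-12 * nd$n) {
        cand <- sp; cand_id <- nd$id
      }
    }
    if (is.null(cand)) break
    l <- new_node(cand$left_idx)
    r <- new_node(cand$right_idx)
    nodes[[cand_id]]$leaf <- FALSE
    nodes[[cand_id]]$feature <- cand$feature
    nodes[[cand_id]]$threshold <- cand$threshold
    nodes[[cand_id]]$left <- l
    nodes[[cand_id]]$right <- r
    splits_used <- splits_used + 1L
  }
  tab <- do.call(rbind, lapply(nodes, function(nd) {
    data.frame(id = nd$id, feature = nd$feature, threshold = nd$threshold,
               left = nd$left, right = nd$right, n = nd$n, n_pos = nd$n_pos,
               pos_frac = nd$n_pos / nd$n, leaf = nd$leaf,
               pred = nd$n_pos / nd$n > 0.5, stringsAsFactors = FALSE)
  }))
  structure(tab, class = c("if_cart", "data.frame"),
            predictors = predictors, label = label,
            constraints = list(max_splits = max_splits,
                               min_split_size = min_split_size),
            n_splits = splits_used)
}

#' @export
print.if_cart <- function(x, ...) {
  cat(sprintf("<if_cart> %d split(s), %d leaves, n = %d\n",
              attr(x, "n_splits"), sum(x$leaf), x$n[1]))
  recurse <- function(id, depth) {
    nd <- x[x$id == id, ]
    pad <- strrep("  ", depth)
    if (nd$leaf) {
      cat(sprintf("%s* %s (n = %d, pos = %.2f)\n", pad,
                  if (nd$pred) "low" else "normal", nd$n, nd$pos_frac))
    } else {
      cat(sprintf("%s%s < %.4g ?\n", pad, nd$feature, nd$threshold))
      recurse(nd$left, depth + 1L)
      recurse(nd$right, depth + 1L)
    }
  }
  recurse(1L, 0L)
  invisible(x)
}

#' Predict with a constrained CART tree
#'
#' Routes each row down the tree (`<` left, `>=` right) and returns the
#' leaf's majority label and positive-class fraction (the ranking score).
#'
#' @param object An `if_cart` tree.
#' @param newdata Data frame holding all predictor columns used by the tree.
#' @param ... Unused.
#' @return Data frame with `label` (logical, `TRUE` = positive/low LVEF)
#'   and `score` (leaf positive-class fraction).
#' @export
predict.if_cart <- function(object, newdata, ...) {
  used <- unique(object$feature[!object$leaf])
  missing_cols <- setdiff(used, names(newdata))
  if (length(missing_cols))
    abort_data(paste0("newdata lacks features: ",
                      paste(missing_cols, collapse = ", ")))
  route <- function(row) {
    id <- 1L
    repeat {
      nd <- object[object$id == id, ]
      if (nd$leaf) return(c(nd$pred, nd$pos_frac))
      id <- if (row[[nd$feature]] < nd$threshold) nd$left else nd$right
    }
  }
  res <- t(vapply(seq_len(nrow(newdata)),
                  function(i) route(newdata[i, , drop = FALSE]), numeric(2)))
  data.frame(label = as.logical(res[, 1]), score = res[, 2])
}

#' Serialize a tree to JSON
#'
#' @param tree An `if_cart`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(schema = "ifscreen-cart/1",
              predictors = attr(tree, "predictors"),
              constraints = attr(tree, "constraints"),
              nodes = as.data.frame(tree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a tree serialized by [write_tree_json()]
#' @param path JSON path.
#' @return An `if_cart`.
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "ifscreen-cart/1"))
    abort_malformed("not an ifscreen-cart/1 JSON file")
  tab <- as.data.frame(obj$nodes)
  structure(tab, class = c("if_cart", "data.frame"),
            predictors = obj$predictors,
            constraints = obj$constraints,
            n_splits = sum(!tab$leaf))
}

#' Load one of the published fixed rule trees
#'
#' The two published screening rules ship as versioned JSON fixtures under
#' `inst/extdata`. These rule trees use explicit comparison operators
#' (matching the printed strict inequalities) and are evaluated by
#' [classify_rule_tree()]; [classify_fixed_tree_A()] and
#' [classify_fixed_tree_B()] are the hard-coded equivalents.
#'
#' @param which `"A"` (omega1, age, phi1) or `"B"` (omega1, omegai1).
#' @return A nested rule-tree list.
#' @export
load_fixed_tree <- function(which = c("A", "B")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("fixed_tree_", which, ".json"),
                      package = "ifscreen")
  if (!nzchar(path)) abort_data("fixture not found; is the package installed?")
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Evaluate a rule tree on feature rows
#'
#' @param tree A rule tree from [load_fixed_tree()].
#' @param data Data frame of features named as in the tree.
#' @return Character vector of labels.
#' @export
classify_rule_tree <- function(tree, data) {
  eval_node <- function(node, row) {
    if (!is.null(node$label)) return(node$label)
    x <- row[[node$feature]]
    ok <- switch(node$op,
                 "<" = x < node$threshold,
                 "<=" = x <= node$threshold,
                 ">" = x > node$threshold,
                 ">=" = x >= node$threshold,
                 abort_malformed(paste0("bad op: ", node$op)))
    eval_node(if (ok) node$if_true else node$if_false, row)
  }
  vapply(seq_len(nrow(data)),
         function(i) eval_node(tree$node, data[i, , drop = FALSE]),
         character(1))
}
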