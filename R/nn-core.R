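# Minimal computational-graph engine for 3D convolutional regression
# networks: explicit forward/backward per layer, no external autodiff.
#
# A model is a list of nodes in topological order. Each node:
#   op      layer type
#   inputs  integer ids of predecessor nodes
#   p       named list of parameter arrays (W, b, gamma, beta)
#   h       hyperparameters (stride, pad, kernel, name, ...)
#   buf     non-learned state (batch-norm running statistics)
#
# Activations are (D, H, W, C, N) arrays; feature vectors are (width, N)
# matrices. All randomness goes through R's RNG, so builds and training are
# reproducible under set.seed().

new_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()
  g
}

add_node <- function(g, op, inputs = integer(0), p = list(), h = list(),
                     buf = list()) {
  # force all arguments before taking the next id: nested builder calls in
  # `inputs`/`p` append their own nodes as a side effect
  inputs <- as.integer(inputs)
  force(p); force(h); force(buf)
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(op = op, inputs = inputs, p = p, h = h, buf = buf)
  id
}

he_conv <- function(kern, cin, cout) {
  fan_in <- prod(kern) * cin
  array(rnorm(prod(kern) * cin * cout, 0, sqrt(2 / fan_in)),
        c(kern, cin, cout))
}

he_fc <- function(nin, nout, gain = sqrt(2)) {
  matrix(rnorm(nin * nout, 0, gain / sqrt(nin)), nout, nin)
}

g_conv <- function(g, x, cin, cout, kern = c(3L, 3L, 3L), stride = 1L,
                   pad = NULL) {
  kern <- rep(as.integer(kern), length.out = 3L)
  stride <- rep(as.integer(stride), length.out = 3L)
  if (is.null(pad)) pad <- kern %/% 2L
  pad <- rep(as.integer(pad), length.out = 3L)
  add_node(g, "conv", x,
           p = list(W = he_conv(kern, cin, cout), b = numeric(cout)),
           h = list(stride = stride, pad = pad))
}

g_dwconv <- function(g, x, channels, kern = c(3L, 3L, 3L), stride = 1L) {
  kern <- rep(as.integer(kern), length.out = 3L)
  stride <- rep(as.integer(stride), length.out = 3L)
  add_node(g, "dwconv", x,
           p = list(W = he_conv(kern, 1L, channels), b = numeric(channels)),
           h = list(stride = stride, pad = kern %/% 2L))
}

g_bn <- function(g, x, channels, momentum = 0.1, eps = 1e-5) {
  add_node(g, "bn", x,
           p = list(gamma = rep(1, channels), beta = numeric(channels)),
           h = list(momentum = momentum, eps = eps),
           buf = list(mean = numeric(channels), var = rep(1, channels)))
}

g_relu <- function(g, x) add_node(g, "relu", x)

g_maxpool <- function(g, x, kern = 3L, stride = 2L, pad = 1L) {
  add_node(g, "maxpool", x,
           h = list(kern = rep(as.integer(kern), length.out = 3L),
                    stride = rep(as.integer(stride), length.out = 3L),
                    pad = rep(as.integer(pad), length.out = 3L)))
}

g_gap <- function(g, x) add_node(g, "gap", x)

g_fc <- function(g, x, nin, nout, gain = sqrt(2)) {
  add_node(g, "fc", x, p = list(W = he_fc(nin, nout, gain), b = numeric(nout)))
}

g_add <- function(g, a, b) add_node(g, "add", c(a, b))

g_concat <- function(g, ids) add_node(g, "concat", ids)

g_concat_c <- function(g, ids) add_node(g, "concat_c", ids)

g_input <- function(g, name) add_node(g, "input", h = list(name = name))

# per-channel broadcast of a length-C vector over an (s, C, N)-shaped flat array
bn_bcast <- function(v, s, N) rep(rep(v, each = s), times = N)

# per-channel sum of a (D,H,W,C,N) array
bn_chansum <- function(a, s, C, N) {
  .rowSums(matrix(.colSums(matrix(a, nrow = s), s, C * N), C, N), C, N)
}

net_forward <- function(model, inputs, training = FALSE) {
  nodes <- model$nodes
  nv <- length(nodes)
  vals <- vector("list", nv)
  caches <- vector("list", nv)
  for (i in seq_len(nv)) {
    nd <- nodes[[i]]
    op <- nd$op
    if (op == "input") {
      x <- inputs[[nd$h$name]]
      if (is.null(x)) stop("missing input: ", nd$h$name)
      vals[[i]] <- x
    } else if (op == "conv") {
      vals[[i]] <- .conv3d_fwd(vals[[nd$inputs]], nd$p$W, nd$p$b,
                               nd$h$stride, nd$h$pad)
    } else if (op == "dwconv") {
      vals[[i]] <- .dwconv3d_fwd(vals[[nd$inputs]], nd$p$W, nd$p$b,
                                 nd$h$stride, nd$h$pad)
    } else if (op == "bn") {
      x <- vals[[nd$inputs]]
      d <- dim(x)
      s <- prod(d[1:3]); C <- d[4L]; N <- d[5L]
      if (training) {
        m <- s * N
        mu <- bn_chansum(x, s, C, N) / m
        ex2 <- bn_chansum(x * x, s, C, N) / m
        v <- pmax(ex2 - mu^2, 0)
        mom <- nd$h$momentum
        nodes[[i]]$buf$mean <- (1 - mom) * nd$buf$mean + mom * mu
        nodes[[i]]$buf$var <- (1 - mom) * nd$buf$var + mom * v
      } else {
        mu <- nd$buf$mean
        v <- nd$buf$var
      }
      inv <- 1 / sqrt(v + nd$h$eps)
      xhat <- (x - bn_bcast(mu, s, N)) * bn_bcast(inv, s, N)
      y <- bn_bcast(nd$p$gamma, s, N) * xhat + bn_bcast(nd$p$beta, s, N)
      dim(y) <- d
      vals[[i]] <- y
      caches[[i]] <- list(xhat = xhat, inv = inv, training = training)
    } else if (op == "relu") {
      x <- vals[[nd$inputs]]
      y <- x * (x > 0)
      if (!is.null(dim(x))) dim(y) <- dim(x)
      vals[[i]] <- y
    } else if (op == "maxpool") {
      r <- .maxpool3d_fwd(vals[[nd$inputs]], nd$h$kern, nd$h$stride, nd$h$pad)
      vals[[i]] <- r$y
      caches[[i]] <- list(argmax = r$argmax, xdim = dim(vals[[nd$inputs]]))
    } else if (op == "gap") {
      x <- vals[[nd$inputs]]
      d <- dim(x)
      s <- prod(d[1:3])
      vals[[i]] <- matrix(.colSums(matrix(x, nrow = s), s, d[4L] * d[5L]) / s,
                          d[4L], d[5L])
      caches[[i]] <- list(xdim = d)
    } else if (op == "fc") {
      x <- vals[[nd$inputs]]
      vals[[i]] <- nd$p$W %*% x + nd$p$b
    } else if (op == "add") {
      vals[[i]] <- vals[[nd$inputs[1L]]] + vals[[nd$inputs[2L]]]
    } else if (op == "concat") {
      xs <- lapply(nd$inputs, function(j) vals[[j]])
      vals[[i]] <- do.call(rbind, xs)
      caches[[i]] <- list(rows = vapply(xs, nrow, integer(1)))
    } else if (op == "concat_c") {
      xs <- lapply(nd$inputs, function(j) vals[[j]])
      dims <- lapply(xs, dim)
      Cs <- vapply(dims, `[`, integer(1), 4L)
      d <- dims[[1L]]
      out <- array(0, c(d[1:3], sum(Cs), d[5L]))
      at <- 0L
      for (k in seq_along(xs)) {
        out[, , , (at + 1L):(at + Cs[k]), ] <- xs[[k]]
        at <- at + Cs[k]
      }
      vals[[i]] <- out
      caches[[i]] <- list(channels = Cs)
    } else {
      stop("unknown op: ", op)
    }
  }
  list(out = vals[[model$output_id]], vals = vals, caches = caches,
       nodes = nodes)
}

net_backward <- function(model, vals, caches, dout) {
  nodes <- model$nodes
  nv <- length(nodes)
  gout <- vector("list", nv)
  pgrads <- vector("list", nv)
  gout[[model$output_id]] <- dout
  acc <- function(j, g) {
    gout[[j]] <<- if (is.null(gout[[j]])) g else gout[[j]] + g
  }
  for (i in rev(seq_len(nv))) {
    dy <- gout[[i]]
    if (is.null(dy)) next
    nd <- nodes[[i]]
    op <- nd$op
    if (op == "input") {
      next
    } else if (op == "conv") {
      r <- .conv3d_bwd(vals[[nd$inputs]], nd$p$W, dy, nd$h$stride, nd$h$pad)
      pgrads[[i]] <- list(W = r$dw, b = r$db)
      acc(nd$inputs, r$dx)
    } else if (op == "dwconv") {
      r <- .dwconv3d_bwd(vals[[nd$inputs]], nd$p$W, dy, nd$h$stride, nd$h$pad)
      pgrads[[i]] <- list(W = r$dw, b = r$db)
      acc(nd$inputs, r$dx)
    } else if (op == "bn") {
      cc <- caches[[i]]
      d <- dim(vals[[i]])
      s <- prod(d[1:3]); C <- d[4L]; N <- d[5L]
      dgamma <- bn_chansum(dy * cc$xhat, s, C, N)
      dbeta <- bn_chansum(dy, s, C, N)
      pgrads[[i]] <- list(gamma = dgamma, beta = dbeta)
      gi <- bn_bcast(nd$p$gamma * cc$inv, s, N)
      if (cc$training) {
        m <- s * N
        dx <- gi * (dy - bn_bcast(dbeta / m, s, N) -
                      cc$xhat * bn_bcast(dgamma / m, s, N))
      } else {
        dx <- gi * dy
      }
      dim(dx) <- d
      acc(nd$inputs, dx)
    } else if (op == "relu") {
      acc(nd$inputs, dy * (vals[[i]] > 0))
    } else if (op == "maxpool") {
      cc <- caches[[i]]
      acc(nd$inputs, .maxpool3d_bwd(dy, cc$argmax, cc$xdim))
    } else if (op == "gap") {
      d <- caches[[i]]$xdim
      s <- prod(d[1:3])
      dx <- array(rep(as.numeric(dy) / s, each = s), d)
      acc(nd$inputs, dx)
    } else if (op == "fc") {
      x <- vals[[nd$inputs]]
      pgrads[[i]] <- list(W = dy %*% t(x), b = .rowSums(dy, nrow(dy), ncol(dy)))
      acc(nd$inputs, crossprod(nd$p$W, dy))
    } else if (op == "add") {
      acc(nd$inputs[1L], dy)
      acc(nd$inputs[2L], dy)
    } else if (op == "concat") {
      rows <- caches[[i]]$rows
      at <- 0L
      for (k in seq_along(nd$inputs)) {
        acc(nd$inputs[k], dy[(at + 1L):(at + rows[k]), , drop = FALSE])
        at <- at + rows[k]
      }
    } else if (op == "concat_c") {
      Cs <- caches[[i]]$channels
      at <- 0L
      for (k in seq_along(nd$inputs)) {
        acc(nd$inputs[k], dy[, , , (at + 1L):(at + Cs[k]), , drop = FALSE])
        at <- at + Cs[k]
      }
    }
  }
  pgrads
}

# Flat access to learnable parameters, keyed "node<id>.<name>".
net_params <- function(model) {
  out <- list()
  for (i in seq_along(model$nodes)) {
    p <- model$nodes[[i]]$p
    for (nm in names(p)) out[[sprintf("node%03d.%s", i, nm)]] <- p[[nm]]
  }
  out
}

net_set_params <- function(model, params) {
  for (key in names(params)) {
    i <- as.integer(sub("^node([0-9]+)\\..*$", "\\1", key))
    nm <- sub("^node[0-9]+\\.", "", key)
    model$nodes[[i]]$p[[nm]] <- params[[key]]
  }
  model
}

net_num_params <- function(model) {
  sum(vapply(net_params(model), length, numeric(1)))
}
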