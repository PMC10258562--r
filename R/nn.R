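# Minimal multilayer-perceptron machinery: dense layers with optional batch
# normalization, explicit forward caches, reverse-mode gradients, Adam
# updates over nested parameter lists, and the classification / Gaussian
# losses used by the model. All shapes are row-major: a batch is an n x p
# matrix, weights are in x out.

.actF <- function(a, act) {
    switch(act,
           relu = pmax(a, 0),
           tanh = tanh(a),
           linear = a,
           stop(sprintf("unknown activation '%s'", act)))
}

.actGrad <- function(a, act) {
    switch(act,
           relu = (a > 0) * 1,
           tanh = 1 - tanh(a)^2,
           linear = array(1, dim = dim(a)),
           stop(sprintf("unknown activation '%s'", act)))
}

.bnEps <- 1e-5

# sizes: integer vector length L+1 (input, hidden..., output);
# acts: character length L; bn: logical length L (normalize the
# pre-activation of layer l with learnable scale/shift and running stats).
# Kaiming-style weight scaling for relu, Xavier otherwise.
nnInit <- function(sizes, acts, bn = rep(FALSE, length(acts))) {
    L <- length(acts)
    stopifnot(length(sizes) == L + 1, length(bn) == L)
    W <- vector("list", L); b <- vector("list", L)
    g <- vector("list", L); be <- vector("list", L)
    rm <- vector("list", L); rv <- vector("list", L)
    for (l in seq_len(L)) {
        fanIn <- sizes[l]
        sc <- if (acts[l] == "relu") sqrt(2 / fanIn) else sqrt(1 / fanIn)
        W[[l]] <- matrix(rnorm(fanIn * sizes[l + 1], sd = sc),
                         fanIn, sizes[l + 1])
        b[[l]] <- numeric(sizes[l + 1])
        if (bn[l]) {
            g[[l]] <- rep(1, sizes[l + 1]); be[[l]] <- numeric(sizes[l + 1])
            rm[[l]] <- numeric(sizes[l + 1]); rv[[l]] <- rep(1, sizes[l + 1])
        } else {
            g[[l]] <- numeric(0); be[[l]] <- numeric(0)
            rm[[l]] <- numeric(0); rv[[l]] <- numeric(0)
        }
    }
    list(W = W, b = b, g = g, be = be, rm = rm, rv = rv, act = acts, bn = bn)
}

# train = TRUE uses batch statistics in the normalized layers (and reports
# them in the cache so the caller can refresh the running estimates);
# train = FALSE uses the stored running statistics (deterministic eval).
nnForward <- function(net, X, cache = FALSE, train = FALSE) {
    L <- length(net$W)
    H <- vector("list", L + 1)
    A <- vector("list", L)         # post-BN pre-activation
    Ahat <- vector("list", L)      # normalized pre-activation (BN layers)
    mu <- vector("list", L); v <- vector("list", L)
    H[[1]] <- X
    for (l in seq_len(L)) {
        a <- sweep(H[[l]] %*% net$W[[l]], 2, net$b[[l]], `+`)
        if (net$bn[l]) {
            if (train) {
                m <- colMeans(a)
                s2 <- colMeans(sweep(a, 2, m)^2)
            } else {
                m <- net$rm[[l]]; s2 <- net$rv[[l]]
            }
            ah <- sweep(sweep(a, 2, m), 2, sqrt(s2 + .bnEps), `/`)
            a <- sweep(sweep(ah, 2, net$g[[l]], `*`), 2, net$be[[l]], `+`)
            Ahat[[l]] <- ah; mu[[l]] <- m; v[[l]] <- s2
        }
        A[[l]] <- a
        H[[l + 1]] <- .actF(a, net$act[l])
    }
    if (cache) list(out = H[[L + 1]], H = H, A = A, Ahat = Ahat,
                    mu = mu, v = v, train = train)
    else H[[L + 1]]
}

# dOut: gradient of the scalar objective w.r.t. the network output.
# Returns parameter gradients (W, b, g, be) and the input gradient dX.
# The cache must come from a forward pass with matching `train` mode.
nnBackward <- function(net, fw, dOut) {
    L <- length(net$W)
    dW <- vector("list", L); db <- vector("list", L)
    dg <- vector("list", L); dbe <- vector("list", L)
    for (l in rev(seq_len(L))) {
        dA <- dOut * .actGrad(fw$A[[l]], net$act[l])
        if (net$bn[l]) {
            ah <- fw$Ahat[[l]]
            dg[[l]] <- colSums(dA * ah)
            dbe[[l]] <- colSums(dA)
            dah <- sweep(dA, 2, net$g[[l]], `*`)
            sd <- sqrt(fw$v[[l]] + .bnEps)
            if (fw$train) {
                n <- nrow(dA)
                t1 <- dah
                t2 <- matrix(colMeans(dah), n, ncol(dA), byrow = TRUE)
                t3 <- ah * matrix(colMeans(dah * ah), n, ncol(dA),
                                  byrow = TRUE)
                dA <- sweep(t1 - t2 - t3, 2, sd, `/`)
            } else {
                dA <- sweep(dah, 2, sd, `/`)
            }
        } else {
            dg[[l]] <- numeric(0); dbe[[l]] <- numeric(0)
        }
        dW[[l]] <- crossprod(fw$H[[l]], dA)
        db[[l]] <- colSums(dA)
        dOut <- tcrossprod(dA, net$W[[l]])
    }
    list(W = dW, b = db, g = dg, be = dbe, dX = dOut)
}

# Exponential-moving-average refresh of the running batch-norm statistics
# from a training-mode forward cache.
nnUpdateRunning <- function(net, fw, momentum = 0.9) {
    for (l in seq_along(net$W)) {
        if (!net$bn[l]) next
        net$rm[[l]] <- momentum * net$rm[[l]] + (1 - momentum) * fw$mu[[l]]
        net$rv[[l]] <- momentum * net$rv[[l]] + (1 - momentum) * fw$v[[l]]
    }
    net
}

# ---- Adam over nested numeric lists --------------------------------------

adamInit <- function(params) {
    walk <- function(p) {
        if (is.list(p)) lapply(p, walk)
        else list(m = p * 0, v = p * 0)
    }
    list(state = walk(params), t = 0L)
}

# Decays L2-style: wd * p is added to the raw gradient.
adamStep <- function(params, grads, opt, lr, wd = 0,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    opt$t <- opt$t + 1L
    t <- opt$t
    walk <- function(p, g, s) {
        if (is.list(p)) {
            for (k in seq_along(p)) {
                r <- walk(p[[k]], g[[k]], s[[k]])
                p[[k]] <- r$p; s[[k]] <- r$s
            }
            return(list(p = p, s = s))
        }
        if (length(p) == 0) return(list(p = p, s = s))
        g <- g + wd * p
        s$m <- beta1 * s$m + (1 - beta1) * g
        s$v <- beta2 * s$v + (1 - beta2) * g^2
        mh <- s$m / (1 - beta1^t)
        vh <- s$v / (1 - beta2^t)
        list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
    }
    r <- walk(params, grads, opt$state)
    list(params = r$p, opt = list(state = r$s, t = t))
}

# ---- losses ---------------------------------------------------------------

softplus <- function(v) ifelse(v > 30, v, log1p(exp(pmin(v, 30))))

# Per-sample softmax cross-entropy. y: integer class index per row.
# dlogits is unscaled: row i is the gradient of loss_i w.r.t. logits_i.
softmaxCE <- function(logits, y) {
    mx <- apply(logits, 1, max)
    sh <- logits - mx
    lse <- log(rowSums(exp(sh)))
    n <- nrow(logits)
    loss <- lse - sh[cbind(seq_len(n), y)]
    P <- exp(sh - lse)
    dlogits <- P
    dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
    list(loss = loss, dlogits = dlogits, prob = P)
}

# Per-sample multi-label binary cross-entropy, averaged over labels.
# Y: n x M binary indicator matrix.
bceLogits <- function(logits, Y) {
    M <- ncol(logits)
    p <- 1 / (1 + exp(-logits))
    ll <- softplus(logits) - Y * logits  # = -[y log p + (1-y) log(1-p)]
    loss <- rowMeans(ll)
    dlogits <- (p - Y) / M
    list(loss = loss, dlogits = dlogits, prob = p)
}
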