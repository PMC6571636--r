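#include <Rcpp.h>
using namespace Rcpp;

// Joint Kohonen / counter-propagation training loop.
//
// X      n x m input matrix (autoscaled descriptors)
// Y      n x g one-hot target matrix, or NULL for an unsupervised SOM
// W0     k x m initial Kohonen weights, neurons in row-major grid order
// U0     k x g initial output-layer weights (ignored when Y is NULL)
// order  t_max x n matrix of 1-based presentation orders, one row per epoch
// rows, cols  grid dimensions (k == rows * cols)
// a_max, a_min  learning-rate bounds of the linear schedule
//
// The learning rate decays linearly from a_max (t = 1) to a_min (t = t_max);
// the neighbourhood radius shrinks linearly from max(rows, cols) - 1 to 0.
// Neurons within Chebyshev distance d <= radius of the winner move toward
// the input by eta(t) * (1 - d / (radius + 1)); with targets present the
// output weights of the same neurons move toward y by the same factor.
// Ties in the winner search resolve to the first neuron in row-major order.
//
// Returns the trained weights plus the per-epoch mean quantization error
// (mean Euclidean distance of each presented object to its winner at
// presentation time).
// [[Rcpp::export]]
List cpann_train_core(NumericMatrix X, Nullable<NumericMatrix> Y_,
                      NumericMatrix W0, Nullable<NumericMatrix> U0_,
                      IntegerMatrix order, int rows, int cols,
                      double a_max, double a_min) {
  const int n = X.nrow(), m = X.ncol();
  const int k = rows * cols;
  if (W0.nrow() != k || W0.ncol() != m)
    stop("weight matrix does not match grid and input dimensions");
  if (order.ncol() != n)
    stop("presentation order does not cover the data");

  const bool supervised = Y_.isNotNull();
  NumericMatrix W = clone(W0);
  NumericMatrix Y, U;
  int g = 0;
  if (supervised) {
    Y = as<NumericMatrix>(Y_);
    if (U0_.isNull()) stop("output-layer weights required with targets");
    U = clone(as<NumericMatrix>(U0_));
    g = U.ncol();
    if (Y.nrow() != n || Y.ncol() != g)
      stop("target matrix does not match data and output layer");
  }

  const int t_max = order.nrow();
  NumericVector qe(t_max);
  const double r_max = std::max(rows, cols) - 1.0;

  for (int t = 1; t <= t_max; ++t) {
    const double frac = (t_max == 1) ? 0.0
      : (double)(t_max - t) / (double)(t_max - 1);
    // single-epoch runs train at a_max with the winner only
    const double eta = (t_max == 1) ? a_max : (a_max - a_min) * frac + a_min;
    const double radius = r_max * frac;
    double qsum = 0.0;

    for (int s = 0; s < n; ++s) {
      const int i = order(t - 1, s) - 1;
      if (i < 0 || i >= n) stop("presentation order index out of range");

      int win = 0;
      double best = R_PosInf;
      for (int j = 0; j < k; ++j) {
        double d = 0.0;
        for (int c = 0; c < m; ++c) {
          const double diff = X(i, c) - W(j, c);
          d += diff * diff;
        }
        if (d < best) { best = d; win = j; }
      }
      qsum += std::sqrt(best);

      const int wr = win / cols, wc = win % cols;
      for (int j = 0; j < k; ++j) {
        const int dr = std::abs(j / cols - wr);
        const int dc = std::abs(j % cols - wc);
        const int d = dr > dc ? dr : dc;
        if ((double)d <= radius) {
          const double f = eta * (1.0 - (double)d / (radius + 1.0));
          for (int c = 0; c < m; ++c)
            W(j, c) += f * (X(i, c) - W(j, c));
          if (supervised)
            for (int q = 0; q < g; ++q)
              U(j, q) += f * (Y(i, q) - U(j, q));
        }
      }
    }
    qe[t - 1] = qsum / n;
  }

  List out = List::create(_["weights"] = W, _["qe"] = qe);
  if (supervised) out["output_weights"] = U;
  return out;
}

// Winner indices (1-based, row-major) and Euclidean distances for each row
// of X against the neuron weight matrix W.
// [[Rcpp::export]]
List map_winners_core(NumericMatrix X, NumericMatrix W) {
  const int n = X.nrow(), m = X.ncol(), k = W.nrow();
  if (W.ncol() != m) stop("dimension mismatch between data and weights");
  IntegerVector win(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    int best_j = 0;
    double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      double d = 0.0;
      for (int c = 0; c < m; ++c) {
        const double diff = X(i, c) - W(j, c);
        d += diff * diff;
      }
      if (d < best) { best = d; best_j = j; }
    }
    win[i] = best_j + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["winner"] = win, _["distance"] = dist);
}
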