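// Forward and backward passes for the stack-and-pad CNN:
//   input (H x W, one channel) -> conv 3x3 (8 ch) -> ReLU
//   -> conv 3x3 (16 ch) -> ReLU -> adaptive max pool to 4x4
//   -> fc 256 -> 64 -> ReLU -> fc 64 -> n_out
// Convolutions use zero 'same' padding. The input is the trimmed feature
// stack (trailing all-zero padding rows removed by the caller), which makes
// outputs exactly invariant to extra zero-row padding.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

// column-major tensors indexed [h + H*w + H*W*c]
inline int idx3(int h, int w, int c, int H, int W) { return h + H * w + H * W * c; }
// conv weights stored as R array dim (3, 3, Cin, Cout): [di + 3*dj + 9*ic + 9*Cin*oc]
inline int widx(int di, int dj, int ic, int oc, int Cin) {
  return di + 3 * dj + 9 * ic + 9 * Cin * oc;
}

// shift-and-add 'same'-padded 3x3 convolution: for each tap (di, dj) the
// inner loop is a contiguous fused multiply-add over the h dimension
void convForward(const std::vector<double>& x, int H, int W, int Cin,
                 const double* wt, const double* b, int Cout,
                 std::vector<double>& z) {
  z.resize((size_t)H * W * Cout);
  for (int oc = 0; oc < Cout; ++oc)
    std::fill(z.begin() + (size_t)oc * H * W,
              z.begin() + (size_t)(oc + 1) * H * W, b[oc]);
  for (int oc = 0; oc < Cout; ++oc)
    for (int ic = 0; ic < Cin; ++ic)
      for (int dj = 0; dj < 3; ++dj) {
        int w0 = std::max(0, 1 - dj), w1 = std::min(W, W + 1 - dj);
        for (int di = 0; di < 3; ++di) {
          double wv = wt[widx(di, dj, ic, oc, Cin)];
          if (wv == 0.0) continue;
          int h0 = std::max(0, 1 - di), h1 = std::min(H, H + 1 - di);
          for (int w = w0; w < w1; ++w) {
            const double* xs = &x[idx3(h0 + di - 1, w + dj - 1, ic, H, W)];
            double* zs = &z[idx3(h0, w, oc, H, W)];
            for (int h = 0; h < h1 - h0; ++h) zs[h] += wv * xs[h];
          }
        }
      }
}

// gradient wrt weights/bias and (optionally) input, same shift-and-add form
void convBackward(const std::vector<double>& x, int H, int W, int Cin,
                  const double* wt, int Cout, const std::vector<double>& dz,
                  double* dwt, double* db, std::vector<double>* dx) {
  if (dx) dx->assign((size_t)H * W * Cin, 0.0);
  for (int oc = 0; oc < Cout; ++oc) {
    const double* dzc = &dz[(size_t)oc * H * W];
    double acc = 0.0;
    for (size_t t = 0; t < (size_t)H * W; ++t) acc += dzc[t];
    db[oc] += acc;
  }
  for (int oc = 0; oc < Cout; ++oc)
    for (int ic = 0; ic < Cin; ++ic)
      for (int dj = 0; dj < 3; ++dj) {
        int w0 = std::max(0, 1 - dj), w1 = std::min(W, W + 1 - dj);
        for (int di = 0; di < 3; ++di) {
          int h0 = std::max(0, 1 - di), h1 = std::min(H, H + 1 - di);
          double wacc = 0.0;
          double wv = wt[widx(di, dj, ic, oc, Cin)];
          for (int w = w0; w < w1; ++w) {
            const double* xs = &x[idx3(h0 + di - 1, w + dj - 1, ic, H, W)];
            const double* gs = &dz[idx3(h0, w, oc, H, W)];
            if (dx) {
              double* ds = &(*dx)[idx3(h0 + di - 1, w + dj - 1, ic, H, W)];
              for (int h = 0; h < h1 - h0; ++h) {
                wacc += gs[h] * xs[h];
                ds[h] += gs[h] * wv;
              }
            } else {
              for (int h = 0; h < h1 - h0; ++h) wacc += gs[h] * xs[h];
            }
          }
          dwt[widx(di, dj, ic, oc, Cin)] += wacc;
        }
      }
}

inline void relu(std::vector<double>& v) {
  for (size_t i = 0; i < v.size(); ++i) if (v[i] < 0) v[i] = 0;
}

// PyTorch-style adaptive pooling region [floor(i*n/o), ceil((i+1)*n/o))
inline int regionStart(int i, int n, int o) { return (int)std::floor((double)i * n / o); }
inline int regionEnd(int i, int n, int o) { return (int)std::ceil((double)(i + 1) * n / o); }

struct ForwardState {
  int H, W, C1, C2, Ph, Pw, nHid, nOut;
  std::vector<double> x, a1, a2, pooled, hid, out;
  std::vector<int> argmax;  // flat index into a2 per pooled cell
};

void forwardPass(const NumericMatrix& xin, const List& params, ForwardState& S) {
  NumericVector W1 = params["W1"], b1 = params["b1"];
  NumericVector W2 = params["W2"], b2 = params["b2"];
  NumericMatrix Wf1 = params["Wf1"];
  NumericVector bf1 = params["bf1"];
  NumericMatrix Wf2 = params["Wf2"];
  NumericVector bf2 = params["bf2"];
  IntegerVector dim1 = W1.attr("dim"), dim2 = W2.attr("dim");
  IntegerVector pool = params["pool"];  // c(rows, cols) of the adaptive grid
  S.H = xin.nrow(); S.W = xin.ncol();
  S.C1 = dim1[3]; S.C2 = dim2[3];
  S.Ph = pool[0]; S.Pw = pool[1];
  S.nHid = Wf1.nrow(); S.nOut = Wf2.nrow();

  S.x.assign(xin.begin(), xin.end());
  std::vector<double> z1;
  convForward(S.x, S.H, S.W, 1, W1.begin(), b1.begin(), S.C1, z1);
  S.a1 = z1; relu(S.a1);
  std::vector<double> z2;
  convForward(S.a1, S.H, S.W, S.C1, W2.begin(), b2.begin(), S.C2, z2);
  S.a2 = z2; relu(S.a2);

  int Ph = S.Ph, Pw = S.Pw;
  S.pooled.assign((size_t)S.C2 * Ph * Pw, 0.0);
  S.argmax.assign((size_t)S.C2 * Ph * Pw, -1);
  for (int c = 0; c < S.C2; ++c)
    for (int ri = 0; ri < Ph; ++ri)
      for (int rj = 0; rj < Pw; ++rj) {
        int hs = regionStart(ri, S.H, Ph), he = regionEnd(ri, S.H, Ph);
        int ws = regionStart(rj, S.W, Pw), we = regionEnd(rj, S.W, Pw);
        double best = -1e300; int bi = -1;
        for (int w = ws; w < we; ++w)
          for (int h = hs; h < he; ++h) {
            double v = S.a2[idx3(h, w, c, S.H, S.W)];
            if (v > best) { best = v; bi = idx3(h, w, c, S.H, S.W); }
          }
        int k = c * Ph * Pw + ri * Pw + rj;
        S.pooled[k] = best; S.argmax[k] = bi;
      }

  S.hid.assign(S.nHid, 0.0);
  int nFlat = S.C2 * Ph * Pw;
  for (int i = 0; i < S.nHid; ++i) {
    double acc = bf1[i];
    for (int j = 0; j < nFlat; ++j) acc += Wf1(i, j) * S.pooled[j];
    S.hid[i] = acc > 0 ? acc : 0;
  }
  S.out.assign(S.nOut, 0.0);
  for (int i = 0; i < S.nOut; ++i) {
    double acc = bf2[i];
    for (int j = 0; j < S.nHid; ++j) acc += Wf2(i, j) * S.hid[j];
    S.out[i] = acc;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cnn_forward_cpp(NumericMatrix x, List params) {
  ForwardState S;
  forwardPass(x, params, S);
  return NumericVector(S.out.begin(), S.out.end());
}

// Returns output plus parameter gradients for one sample given d(loss)/d(out).
// [[Rcpp::export]]
List cnn_backward_cpp(NumericMatrix x, List params, NumericVector dout) {
  ForwardState S;
  forwardPass(x, params, S);
  NumericVector W1 = params["W1"], W2 = params["W2"];
  NumericMatrix Wf1 = params["Wf1"], Wf2 = params["Wf2"];

  NumericVector dW1(W1.size()), db1(S.C1), dW2(W2.size()), db2(S.C2);
  dW1.attr("dim") = W1.attr("dim");
  dW2.attr("dim") = W2.attr("dim");
  NumericMatrix dWf1(Wf1.nrow(), Wf1.ncol()), dWf2(Wf2.nrow(), Wf2.ncol());
  NumericVector dbf1(S.nHid), dbf2(S.nOut);

  int nFlat = S.C2 * S.Ph * S.Pw;
  // fc2
  std::vector<double> dhid(S.nHid, 0.0);
  for (int i = 0; i < S.nOut; ++i) {
    double g = dout[i];
    dbf2[i] += g;
    for (int j = 0; j < S.nHid; ++j) {
      dWf2(i, j) += g * S.hid[j];
      dhid[j] += g * Wf2(i, j);
    }
  }
  // fc1 (ReLU)
  std::vector<double> dpool(nFlat, 0.0);
  for (int i = 0; i < S.nHid; ++i) {
    if (S.hid[i] <= 0) continue;
    double g = dhid[i];
    dbf1[i] += g;
    for (int j = 0; j < nFlat; ++j) {
      dWf1(i, j) += g * S.pooled[j];
      dpool[j] += g * Wf1(i, j);
    }
  }
  // unpool into a2 (ReLU mask folded in: argmax of a ReLU'd map; gradient
  // passes only where the activation was positive)
  std::vector<double> da2((size_t)S.H * S.W * S.C2, 0.0);
  for (int k = 0; k < nFlat; ++k)
    if (S.argmax[k] >= 0 && S.a2[S.argmax[k]] > 0) da2[S.argmax[k]] += dpool[k];
  // conv2 backward
  std::vector<double> da1;
  convBackward(S.a1, S.H, S.W, S.C1, W2.begin(), S.C2, da2,
               dW2.begin(), db2.begin(), &da1);
  // ReLU mask of a1
  for (size_t i = 0; i < da1.size(); ++i) if (S.a1[i] <= 0) da1[i] = 0;
  // conv1 backward (input gradient not needed)
  convBackward(S.x, S.H, S.W, 1, W1.begin(), S.C1, da1,
               dW1.begin(), db1.begin(), (std::vector<double>*)0);

  return List::create(_["out"] = NumericVector(S.out.begin(), S.out.end()),
                      _["W1"] = dW1, _["b1"] = db1, _["W2"] = dW2, _["b2"] = db2,
                      _["Wf1"] = dWf1, _["bf1"] = dbf1,
                      _["Wf2"] = dWf2, _["bf2"] = dbf2);
}

// Batched wrappers: one call per minibatch keeps allocation overhead out of
// the R training loop.
// [[Rcpp::export]]
NumericMatrix cnn_forward_batch_cpp(List stacks, List params) {
  int n = stacks.size();
  NumericMatrix out;
  for (int i = 0; i < n; ++i) {
    ForwardState S;
    forwardPass(stacks[i], params, S);
    if (i == 0) out = NumericMatrix(n, S.nOut);
    for (int j = 0; j < S.nOut; ++j) out(i, j) = S.out[j];
  }
  return out;
}

// [[Rcpp::export]]
List cnn_backward_batch_cpp(List stacks, List params, NumericMatrix dout) {
  int n = stacks.size();
  List acc;
  for (int i = 0; i < n; ++i) {
    NumericMatrix x = stacks[i];
    NumericVector d = dout(i, _);
    List g = cnn_backward_cpp(x, params, d);
    if (i == 0) {
      acc = g;
    } else {
      const char* nms[] = {"W1", "b1", "W2", "b2", "Wf1", "bf1", "Wf2", "bf2"};
      for (int k = 0; k < 8; ++k) {
        NumericVector a = acc[nms[k]];
        NumericVector b = g[nms[k]];
        for (int t = 0; t < a.size(); ++t) a[t] += b[t];
      }
    }
  }
  return acc;
}
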