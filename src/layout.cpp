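// Spring-electrical refinement for tree layouts.
//
// Attractive forces act along tree edges (magnitude d^2/K toward the
// neighbor), repulsive forces act between all vertex pairs (magnitude
// p*K^2/d), approximated by a Barnes-Hut quadtree with opening criterion
// size/d < theta; theta <= 0 switches to exact pairwise summation.
// Displacement per iteration is step * F/|F| with multiplicative cooling.
// The energy of an iterate is sum |F_v|^2; the minimum-energy iterate
// encountered (including the initial one) is returned, so refinement can
// never end at a higher energy than it started.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double EPS = 1e-9;
const int MAX_DEPTH = 48;

struct QuadTree {
  // node arrays; body >= 0: single-body leaf, -1: empty slot, -2: internal,
  // body <= -3: bucket leaf at max depth, index = -3 - body
  std::vector<int> body;
  std::vector<int> child;     // 4 per node
  std::vector<double> mass, comx, comy, cx, cy, half;
  std::vector<std::vector<int> > buckets;
  const std::vector<double> &px, &py;

  QuadTree(const std::vector<double>& x, const std::vector<double>& y)
      : px(x), py(y) {
    int n = (int)x.size();
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
    for (int i = 1; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    double h = 0.5 * std::max(xmax - xmin, ymax - ymin) + EPS;
    newNode(0.5 * (xmin + xmax), 0.5 * (ymin + ymax), h);
    for (int i = 0; i < n; ++i) insert(i);
    for (size_t k = 0; k < mass.size(); ++k) {
      if (mass[k] > 0) { comx[k] /= mass[k]; comy[k] /= mass[k]; }
    }
  }

  int newNode(double x, double y, double h) {
    body.push_back(-1);
    for (int q = 0; q < 4; ++q) child.push_back(-1);
    mass.push_back(0.0); comx.push_back(0.0); comy.push_back(0.0);
    cx.push_back(x); cy.push_back(y); half.push_back(h);
    return (int)body.size() - 1;
  }

  int quadrant(int node, double x, double y) const {
    return (x >= cx[node] ? 1 : 0) + (y >= cy[node] ? 2 : 0);
  }

  int childFor(int node, int q) {
    int c = child[4 * node + q];
    if (c < 0) {
      double h = 0.5 * half[node];
      double nx = cx[node] + (q & 1 ? h : -h);
      double ny = cy[node] + (q & 2 ? h : -h);
      c = newNode(nx, ny, h);
      child[4 * node + q] = c;
    }
    return c;
  }

  void insert(int i) {
    int node = 0, depth = 0;
    for (;;) {
      mass[node] += 1.0; comx[node] += px[i]; comy[node] += py[i];
      if (body[node] == -1 && child[4 * node] < 0 && child[4 * node + 1] < 0 &&
          child[4 * node + 2] < 0 && child[4 * node + 3] < 0 && mass[node] <= 1.0) {
        body[node] = i;               // empty leaf takes the body
        return;
      }
      if (body[node] <= -3) {         // existing bucket
        buckets[-3 - body[node]].push_back(i);
        return;
      }
      if (depth >= MAX_DEPTH) {       // promote to bucket
        std::vector<int> b;
        if (body[node] >= 0) b.push_back(body[node]);
        b.push_back(i);
        buckets.push_back(b);
        body[node] = -3 - (int)(buckets.size() - 1);
        return;
      }
      if (body[node] >= 0) {          // push resident body down
        int j = body[node];
        body[node] = -2;
        int qj = quadrant(node, px[j], py[j]);
        int cj = childFor(node, qj);
        // resident keeps its mass contribution on the path below
        int nodej = cj, depthj = depth + 1;
        for (;;) {
          mass[nodej] += 1.0; comx[nodej] += px[j]; comy[nodej] += py[j];
          if (body[nodej] == -1 && mass[nodej] <= 1.0) { body[nodej] = j; break; }
          if (depthj >= MAX_DEPTH) {
            std::vector<int> b; b.push_back(j);
            buckets.push_back(b);
            body[nodej] = -3 - (int)(buckets.size() - 1);
            break;
          }
          body[nodej] = -2;
          int q2 = quadrant(nodej, px[j], py[j]);
          nodej = childFor(nodej, q2);
          ++depthj;
        }
      } else {
        body[node] = -2;
      }
      int qi = quadrant(node, px[i], py[i]);
      node = childFor(node, qi);
      ++depth;
    }
  }
};

inline void pairRepulse(int i, double xj, double yj, double mj,
                        const std::vector<double>& px, const std::vector<double>& py,
                        double coef, double& fx, double& fy, int jIndex) {
  double dx = px[i] - xj, dy = py[i] - yj;
  double d2 = dx * dx + dy * dy;
  if (d2 < EPS * EPS) {
    // coincident points: deterministic separation along x
    double dir = (jIndex >= 0 && i > jIndex) ? -1.0 : 1.0;
    fx += dir * coef * mj / EPS;
    return;
  }
  double f = coef * mj / d2;  // = p*K^2*m/d * (1/d), applied to (dx, dy)
  fx += f * dx;
  fy += f * dy;
}

void repulseBH(const QuadTree& qt, int i, double theta, double coef,
               double& fx, double& fy) {
  std::vector<int> stack;
  stack.push_back(0);
  while (!stack.empty()) {
    int node = stack.back(); stack.pop_back();
    if (qt.mass[node] <= 0) continue;
    int b = qt.body[node];
    if (b == i) continue;
    if (b >= 0) {
      pairRepulse(i, qt.px[b], qt.py[b], 1.0, qt.px, qt.py, coef, fx, fy, b);
      continue;
    }
    if (b <= -3) {
      const std::vector<int>& bucket = qt.buckets[-3 - b];
      for (size_t t = 0; t < bucket.size(); ++t) {
        int j = bucket[t];
        if (j == i) continue;
        pairRepulse(i, qt.px[j], qt.py[j], 1.0, qt.px, qt.py, coef, fx, fy, j);
      }
      continue;
    }
    // internal node; never approximate a cell containing the body itself
    // (self-interaction), and widen the criterion by the center-of-mass
    // offset from the cell center so off-center masses are not
    // approximated too eagerly
    bool contains = std::fabs(qt.px[i] - qt.cx[node]) <= qt.half[node] &&
                    std::fabs(qt.py[i] - qt.cy[node]) <= qt.half[node];
    double dx = qt.px[i] - qt.comx[node], dy = qt.py[i] - qt.comy[node];
    double d = std::sqrt(dx * dx + dy * dy);
    double ox = qt.comx[node] - qt.cx[node], oy = qt.comy[node] - qt.cy[node];
    double off = std::sqrt(ox * ox + oy * oy);
    if (!contains && d > EPS && (2.0 * qt.half[node] + off) / d < theta) {
      pairRepulse(i, qt.comx[node], qt.comy[node], qt.mass[node],
                  qt.px, qt.py, coef, fx, fy, -1);
    } else {
      for (int q = 0; q < 4; ++q) {
        int c = qt.child[4 * node + q];
        if (c >= 0) stack.push_back(c);
      }
    }
  }
}

double computeForces(const std::vector<double>& px, const std::vector<double>& py,
                     const IntegerMatrix& edges, double theta, double p_rep,
                     double K, std::vector<double>& fx, std::vector<double>& fy) {
  int n = (int)px.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  // attraction along tree edges: |F| = d^2/K => vector (d/K) * (xv - xu)
  int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    double dx = px[v] - px[u], dy = py[v] - py[u];
    double d = std::sqrt(dx * dx + dy * dy);
    double c = d / K;
    fx[u] += c * dx; fy[u] += c * dy;
    fx[v] -= c * dx; fy[v] -= c * dy;
  }
  double coef = p_rep * K * K;
  if (theta <= 0.0) {
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        pairRepulse(i, px[j], py[j], 1.0, px, py, coef, fx[i], fy[i], j);
      }
  } else {
    QuadTree qt(px, py);
    for (int i = 0; i < n; ++i) repulseBH(qt, i, theta, coef, fx[i], fy[i]);
  }
  double energy = 0.0;
  for (int i = 0; i < n; ++i) energy += fx[i] * fx[i] + fy[i] * fy[i];
  return energy;
}

}  // namespace

// [[Rcpp::export]]
List refine_layout_cpp(NumericMatrix pos0, IntegerMatrix edges, int iterations,
                       double step0, double cool, double theta, double p_rep,
                       double K) {
  int n = pos0.nrow();
  std::vector<double> px(n), py(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) { px[i] = pos0(i, 0); py[i] = pos0(i, 1); }
  std::vector<double> bestx = px, besty = py;
  double eInit = computeForces(px, py, edges, theta, p_rep, K, fx, fy);
  double eBest = eInit;
  double step = step0;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) {
      double len = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i]);
      // capped displacement: follow the force directly once it is small
      double scale = (len > step) ? step / len : 1.0;
      px[i] += scale * fx[i];
      py[i] += scale * fy[i];
    }
    step *= cool;
    double e = computeForces(px, py, edges, theta, p_rep, K, fx, fy);
    if (e < eBest) { eBest = e; bestx = px; besty = py; }
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = bestx[i]; out(i, 1) = besty[i]; }
  return List::create(Named("coordinates") = out,
                      Named("energy_initial") = eInit,
                      Named("energy_final") = eBest);
}
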