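// Point-to-triangle closest-point queries accelerated by an axis-aligned
// bounding-box tree over the triangles. Ties between equidistant triangles
// are broken toward the lowest triangle index so queries are deterministic.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}

// Closest point on triangle (a,b,c) to p; Ericson's region classification.
static void closest_pt_triangle(const double* p, const double* a,
                                const double* b, const double* c,
                                double* out) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { out[0]=a[0]; out[1]=a[1]; out[2]=a[2]; return; }

  double bp[3]; vsub(p, b, bp);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { out[0]=b[0]; out[1]=b[1]; out[2]=b[2]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }

  double cp[3]; vsub(p, c, cp);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { out[0]=c[0]; out[1]=c[1]; out[2]=c[2]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k]*v + ac[k]*w;
}

struct BVHNode {
  double bmin[3], bmax[3];
  int left, right;   // child node indices, -1 for leaf
  int start, count;  // range into tri_order for leaves
};

struct MeshBVH {
  std::vector<double> V;   // 3*nv, row-major per vertex
  std::vector<int>    F;   // 3*nf, 0-based
  std::vector<int>    tri_order;
  std::vector<BVHNode> nodes;
  int nv, nf;
};

static const int LEAF_SIZE = 8;

static int build_node(MeshBVH& bvh, std::vector<double>& cent,
                      int start, int count) {
  int idx = (int)bvh.nodes.size();
  bvh.nodes.push_back(BVHNode());
  BVHNode& node = bvh.nodes[idx];
  for (int k = 0; k < 3; ++k) {
    node.bmin[k] = std::numeric_limits<double>::infinity();
    node.bmax[k] = -std::numeric_limits<double>::infinity();
  }
  for (int i = start; i < start + count; ++i) {
    int t = bvh.tri_order[i];
    for (int j = 0; j < 3; ++j) {
      const double* v = &bvh.V[3 * bvh.F[3*t + j]];
      for (int k = 0; k < 3; ++k) {
        if (v[k] < node.bmin[k]) node.bmin[k] = v[k];
        if (v[k] > node.bmax[k]) node.bmax[k] = v[k];
      }
    }
  }
  if (count <= LEAF_SIZE) {
    node.left = node.right = -1;
    node.start = start; node.count = count;
    return idx;
  }
  // split at the median centroid along the widest axis
  double cmin[3], cmax[3];
  for (int k = 0; k < 3; ++k) {
    cmin[k] = std::numeric_limits<double>::infinity();
    cmax[k] = -std::numeric_limits<double>::infinity();
  }
  for (int i = start; i < start + count; ++i) {
    const double* c = &cent[3 * bvh.tri_order[i]];
    for (int k = 0; k < 3; ++k) {
      if (c[k] < cmin[k]) cmin[k] = c[k];
      if (c[k] > cmax[k]) cmax[k] = c[k];
    }
  }
  int axis = 0;
  double ext = cmax[0] - cmin[0];
  for (int k = 1; k < 3; ++k)
    if (cmax[k] - cmin[k] > ext) { ext = cmax[k] - cmin[k]; axis = k; }
  int mid = start + count / 2;
  std::nth_element(bvh.tri_order.begin() + start,
                   bvh.tri_order.begin() + mid,
                   bvh.tri_order.begin() + start + count,
                   [&](int ta, int tb) {
                     double ca = cent[3*ta + axis], cb = cent[3*tb + axis];
                     if (ca != cb) return ca < cb;
                     return ta < tb;   // deterministic ordering
                   });
  int l = build_node(bvh, cent, start, mid - start);
  int r = build_node(bvh, cent, mid, start + count - mid);
  bvh.nodes[idx].left = l;
  bvh.nodes[idx].right = r;
  bvh.nodes[idx].start = -1;
  bvh.nodes[idx].count = 0;
  return idx;
}

static inline double box_dist2(const BVHNode& n, const double* p) {
  double d2 = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (p[k] < n.bmin[k]) d = n.bmin[k] - p[k];
    else if (p[k] > n.bmax[k]) d = p[k] - n.bmax[k];
    d2 += d * d;
  }
  return d2;
}

static void query_point(const MeshBVH& bvh, const double* p,
                        double* best_pt, double& best_d2, int& best_tri) {
  // explicit stack; visit nearer child first for tight pruning
  int stack[128];
  int sp = 0;
  stack[sp++] = 0;
  while (sp > 0) {
    int ni = stack[--sp];
    const BVHNode& node = bvh.nodes[ni];
    if (box_dist2(node, p) > best_d2) continue;
    if (node.left < 0) {
      for (int i = node.start; i < node.start + node.count; ++i) {
        int t = bvh.tri_order[i];
        const double* a = &bvh.V[3 * bvh.F[3*t + 0]];
        const double* b = &bvh.V[3 * bvh.F[3*t + 1]];
        const double* c = &bvh.V[3 * bvh.F[3*t + 2]];
        double q[3];
        closest_pt_triangle(p, a, b, c, q);
        double dx = q[0]-p[0], dy = q[1]-p[1], dz = q[2]-p[2];
        double d2 = dx*dx + dy*dy + dz*dz;
        if (d2 < best_d2 || (d2 == best_d2 && t < best_tri)) {
          best_d2 = d2;
          best_tri = t;
          best_pt[0] = q[0]; best_pt[1] = q[1]; best_pt[2] = q[2];
        }
      }
    } else {
      double dl = box_dist2(bvh.nodes[node.left], p);
      double dr = box_dist2(bvh.nodes[node.right], p);
      // push the farther child first so the nearer one is popped first
      if (dl <= dr) {
        if (sp < 126) { stack[sp++] = node.right; stack[sp++] = node.left; }
      } else {
        if (sp < 126) { stack[sp++] = node.left; stack[sp++] = node.right; }
      }
    }
  }
}

// [[Rcpp::export(name = ".bvh_build")]]
SEXP bvh_build(NumericMatrix V, IntegerMatrix F) {
  if (V.ncol() != 3) stop("vertex matrix must have 3 columns");
  if (F.ncol() != 3) stop("face matrix must have 3 columns");
  MeshBVH* bvh = new MeshBVH();
  bvh->nv = V.nrow();
  bvh->nf = F.nrow();
  bvh->V.resize(3 * bvh->nv);
  for (int i = 0; i < bvh->nv; ++i)
    for (int k = 0; k < 3; ++k) bvh->V[3*i + k] = V(i, k);
  bvh->F.resize(3 * bvh->nf);
  for (int i = 0; i < bvh->nf; ++i)
    for (int k = 0; k < 3; ++k) {
      int vi = F(i, k) - 1;  // R faces are 1-based
      if (vi < 0 || vi >= bvh->nv) { delete bvh; stop("face index out of range"); }
      bvh->F[3*i + k] = vi;
    }
  std::vector<double> cent(3 * bvh->nf);
  for (int i = 0; i < bvh->nf; ++i)
    for (int k = 0; k < 3; ++k)
      cent[3*i + k] = (bvh->V[3*bvh->F[3*i]+k] + bvh->V[3*bvh->F[3*i+1]+k] +
                       bvh->V[3*bvh->F[3*i+2]+k]) / 3.0;
  bvh->tri_order.resize(bvh->nf);
  for (int i = 0; i < bvh->nf; ++i) bvh->tri_order[i] = i;
  bvh->nodes.reserve(2 * bvh->nf / LEAF_SIZE + 4);
  build_node(*bvh, cent, 0, bvh->nf);
  XPtr<MeshBVH> ptr(bvh, true);
  return ptr;
}

// [[Rcpp::export(name = ".bvh_closest")]]
List bvh_closest(SEXP tree, NumericMatrix Q) {
  XPtr<MeshBVH> bvh(tree);
  if (Q.ncol() != 3) stop("query matrix must have 3 columns");
  int n = Q.nrow();
  NumericMatrix pts(n, 3);
  NumericVector dist(n);
  IntegerVector tri(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = { Q(i, 0), Q(i, 1), Q(i, 2) };
    double best_pt[3] = { 0, 0, 0 };
    double best_d2 = std::numeric_limits<double>::infinity();
    int best_tri = std::numeric_limits<int>::max();
    query_point(*bvh, p, best_pt, best_d2, best_tri);
    pts(i, 0) = best_pt[0]; pts(i, 1) = best_pt[1]; pts(i, 2) = best_pt[2];
    dist[i] = std::sqrt(best_d2);
    tri[i] = best_tri + 1;  // back to 1-based
  }
  return List::create(_["point"] = pts, _["distance"] = dist,
                      _["triangle"] = tri);
}
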