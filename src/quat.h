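#ifndef THREADSIM_QUAT_H
#define THREADSIM_QUAT_H

#include <cmath>

// Scalar-first quaternions (w, x, y, z), Hamilton product convention.
// Rotation of a vector v is the sandwich product q * (0, v) * conj(q).

struct Quat {
  double w, x, y, z;
};

inline Quat qmake(double w, double x, double y, double z) {
  Quat q; q.w = w; q.x = x; q.y = y; q.z = z; return q;
}

inline Quat qmul(const Quat &a, const Quat &b) {
  Quat r;
  r.w = a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z;
  r.x = a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y;
  r.y = a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x;
  r.z = a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w;
  return r;
}

inline Quat qconj(const Quat &a) { return qmake(a.w, -a.x, -a.y, -a.z); }

inline double qnorm(const Quat &a) {
  return std::sqrt(a.w * a.w + a.x * a.x + a.y * a.y + a.z * a.z);
}

inline Quat qscale(const Quat &a, double s) {
  return qmake(a.w * s, a.x * s, a.y * s, a.z * s);
}

inline Quat qadd(const Quat &a, const Quat &b) {
  return qmake(a.w + b.w, a.x + b.x, a.y + b.y, a.z + b.z);
}

inline Quat qnormalize(const Quat &a) {
  double n = qnorm(a);
  if (n <= 0.0) return qmake(1.0, 0.0, 0.0, 0.0);
  return qscale(a, 1.0 / n);
}

// R(q) v via sandwich product; homogeneous quadratic in the raw components,
// so constraint Jacobians w.r.t. raw quaternion components are well defined.
inline void qrotate(const Quat &q, const double v[3], double out[3]) {
  Quat p = qmake(0.0, v[0], v[1], v[2]);
  Quat r = qmul(qmul(q, p), qconj(q));
  out[0] = r.x; out[1] = r.y; out[2] = r.z;
}

// d/dq_i of Im(q * (0,v) * conj(q)) for basis component i (0=w,1=x,2=y,3=z).
inline void qrotate_dq(const Quat &q, const double v[3], int i, double out[3]) {
  Quat e = qmake(i == 0, i == 1, i == 2, i == 3);
  Quat p = qmake(0.0, v[0], v[1], v[2]);
  Quat a = qmul(qmul(e, p), qconj(q));
  Quat b = qmul(qmul(q, p), qconj(e));
  out[0] = a.x + b.x; out[1] = a.y + b.y; out[2] = a.z + b.z;
}

#endif
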