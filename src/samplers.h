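#ifndef ORDPG_SAMPLERS_H
#define ORDPG_SAMPLERS_H

double rpg1(double c);
double rpg_int(int b, double c);
double rtnorm1(double mean, double sd, double lower, double upper);

#endif
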