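****************************************************************
Moderation analysis for two-instance repeated measures designs
****************************************************************

Model information
  Outcomes   : pre (instance 1), post (instance 2)
  Difference : pre - post
  Moderators : inflame (continuous, mean-centered)
  Model type : additive (single moderator)
  Sample     : n = 6; rows dropped listwise = 0
  Alpha      : 0.05
  Centering  : inflame at mean 0.3333 (zero is the sample average)

Overall model (difference score)
  R-sq = 0.4857,  F(1, 4) = 3.7778,  p = 0.1239

Coefficients
  term      estimate  se      t        p       ci_low   ci_high
  constant  1.1667    0.2464  4.7348   0.0091  0.4825   1.8508 
  inflame   -0.4857   0.2499  -1.9437  0.1239  -1.1795  0.2081 

Conditional effect of condition ('X') on Y at values of the moderator(s)
  (moderator values on the centered scale; add the stored mean for
   the original scale)
  inflame  estimate  se      t       p       ci_low   ci_high
  -1.0801  1.6913    0.3655  4.6277  0.0098  0.6766   2.7060 
  0.0000   1.1667    0.2464  4.7348  0.0091  0.4825   1.8508 
  0.5167   0.9157    0.2782  3.2918  0.0302  0.1434   1.6881 
  1.0801   0.6420    0.3655  1.7567  0.1538  -0.3727  1.6568 

Conditional effect of moderator(s) on Y in each condition
  Condition 1 (pre):
    term     estimate  se      t        p       ci_low   ci_high
    inflame  -0.2000   0.6740  -0.2967  0.7814  -2.0713  1.6713 
  Condition 2 (post):
    term     estimate  se      t       p       ci_low   ci_high
    inflame  0.2857    0.7423  0.3849  0.7199  -1.7753  2.3467 

Johnson-Neyman procedure
  critical t = 2.7764 at alpha = 0.05, df = 4
  observed moderator range: -1.3333 to 1.6667
  Boundaries of significance:
    boundary  pct_above  boundary_original
    0.6861    16.6667    1.0194           
  Conditional effect of condition across the range:
    W        estimate  se      t       p       ci_low   ci_high  significant
    -1.3333  1.8143    0.4144  4.3780  0.0119  0.6637   2.9649   TRUE       
    -1.1833  1.7414    0.3849  4.5242  0.0106  0.6727   2.8101   TRUE       
    -1.0333  1.6686    0.3569  4.6748  0.0095  0.6776   2.6596   TRUE       
    -0.8833  1.5957    0.3308  4.8235  0.0085  0.6772   2.5142   TRUE       
    -0.7333  1.5229    0.3071  4.9592  0.0077  0.6703   2.3754   TRUE       
    -0.5833  1.4500    0.2863  5.0647  0.0072  0.6551   2.2449   TRUE       
    -0.4333  1.3771    0.2691  5.1167  0.0069  0.6299   2.1244   TRUE       
    -0.2833  1.3043    0.2564  5.0874  0.0070  0.5925   2.0161   TRUE       
    -0.1333  1.2314    0.2486  4.9526  0.0077  0.5411   1.9218   TRUE       
    0.0167   1.1586    0.2464  4.7013  0.0093  0.4744   1.8428   TRUE       
    0.1667   1.0857    0.2499  4.3446  0.0122  0.3919   1.7795   TRUE       
    0.3167   1.0129    0.2588  3.9137  0.0173  0.2943   1.7314   TRUE       
    0.4667   0.9400    0.2726  3.4482  0.0261  0.1831   1.6969   TRUE       
    0.6167   0.8671    0.2906  2.9837  0.0406  0.0602   1.6740   TRUE       
    0.6861   0.8334    0.3002  2.7764  0.0500  0.0000   1.6669   TRUE       
    0.7667   0.7943    0.3121  2.5448  0.0637  -0.0723  1.6609   FALSE      
    0.9167   0.7214    0.3364  2.1443  0.0986  -0.2127  1.6555   FALSE      
    1.0667   0.6486    0.3630  1.7867  0.1485  -0.3593  1.6564   FALSE      
    1.2167   0.5757    0.3914  1.4711  0.2152  -0.5109  1.6623   FALSE      
    1.3667   0.5029    0.4211  1.1941  0.2984  -0.6664  1.6721   FALSE      
    1.5167   0.4300    0.4521  0.9512  0.3954  -0.8251  1.6851   FALSE      
    1.6667   0.3571    0.4839  0.7380  0.5015  -0.9864  1.7007   FALSE      
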