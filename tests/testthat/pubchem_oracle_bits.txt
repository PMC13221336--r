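C1=CC=C(C=C1)C=C[N+](=O)[O-] | 0,9,10,11,14,18,19,178,179,255,283,284,285,301,332,333,344,345,351,355,356,365,370,371,384,395,401,416,423,430,434,441,445,446,449,454,455,470,490,502,516,520,524,552,556,564,570,578,582,584,595,599,603,608,618,634,640,660,664,668,677,678,679,688,708,709,710 
C1=CC=C(C=C1)CC[N+](=O)[O-] | 0,1,9,10,11,14,18,19,178,179,255,283,284,285,301,332,333,344,345,351,355,356,365,370,371,384,395,401,416,423,430,434,441,446,454,455,470,490,514,516,520,524,552,556,564,570,578,582,584,592,595,599,603,607,608,618,634,640,660,664,668,677,678,679,683,688,696,708,709,710 
C1=CC=C(C(=C1)C=C[N+](=O)[O-])[N+](=O)[O-] | 0,9,10,11,14,15,18,19,20,178,179,255,283,284,285,301,332,333,340,344,345,351,355,356,365,370,371,376,377,384,395,401,416,423,430,434,437,441,445,446,449,454,455,464,470,490,502,514,516,520,524,545,546,549,552,556,558,564,570,578,582,584,592,595,599,600,603,607,608,618,633,634,640,660,664,665,668,677,678,679,683,688,708,709,710,758,821 
C=CC1=CC=CC=C1 | 0,1,9,10,11,178,179,255,283,284,332,333,344,355,356,370,371,384,416,430,434,441,446,470,490,516,520,524,552,556,564,570,578,582,584,595,599,603,608,618,634,640,660,664,668,677,678,679,688,708,709,710 
C1=CC=C(C=C1)CCN | 0,1,9,10,11,14,178,179,255,283,284,285,299,332,333,344,345,351,355,356,365,370,371,384,393,416,430,434,441,446,470,490,516,520,524,528,552,556,564,570,578,582,584,592,595,599,603,607,608,618,634,640,643,660,664,668,677,678,679,683,688,696,708,709,710 
C1=CC=C(C=C1)[N+](=O)[O-] | 0,9,10,14,18,19,178,179,255,283,284,285,301,332,340,344,351,355,370,371,376,377,384,395,401,416,423,434,437,441,446,449,454,455,464,470,490,502,514,516,520,524,545,546,549,552,556,558,564,570,578,582,584,592,595,599,600,603,607,608,618,633,634,640,660,664,665,668,677,678,679,683 
C1=CC=C(C=C1)C=CC(=O)O | 0,1,9,10,11,18,19,178,179,255,283,284,286,308,332,333,344,352,355,356,370,371,380,384,406,416,420,430,434,440,441,443,446,452,470,490,516,520,524,552,553,556,564,570,573,578,582,584,595,599,603,608,618,619,634,640,660,664,667,668,671,672,677,678,679,688,708,709,710 
C1OC2=C(O1)C=C(C=C2)C=C[N+](=O)[O-] | 0,9,10,11,14,18,19,20,143,146,178,179,241,244,255,283,284,285,286,301,332,333,341,344,345,351,352,355,356,365,366,367,370,371,380,381,382,384,395,401,405,416,423,430,434,441,445,446,449,454,455,470,476,490,498,502,516,520,524,541,542,544,548,552,556,563,564,565,567,570,573,574,578,582,584,589,594,595,599,603,604,606,608,610,618,619,626,630,634,637,640,641,651,655,660,661,662,664,666,668,677,678,679,680,688,689,699,708,709,710,714,735,761,777,798,824 
COC1=C(C=C(C=C1)C=C[N+](=O)[O-])O | 0,1,9,10,11,14,18,19,20,178,179,255,283,284,285,286,301,308,332,333,341,344,345,351,352,355,356,365,366,370,371,374,381,382,384,395,401,405,406,416,423,430,434,441,445,446,449,454,455,470,476,490,498,502,516,520,524,541,542,544,548,552,556,564,565,567,570,573,574,578,582,584,589,590,594,595,599,603,604,606,608,617,618,619,626,630,631,634,637,640,641,651,655,660,662,663,664,666,667,668,677,678,679,680,688,689,699,708,709,710,714,735,761,777,798,824 
c1ccc2ccccc2c1 | 0,1,9,10,11,178,179,185,186,248,249,255,257,259,283,284,332,333,344,355,356,370,371,384,385,416,430,434,441,446,470,490,516,520,524,552,556,564,570,578,582,584,595,599,603,608,618,634,640,660,664,668,677,678,679,688,696,708,709,710,712,755,818 
C1CC2=CC=CC=C2C1 | 0,1,9,10,11,143,144,178,179,241,242,255,283,284,332,333,344,355,356,370,371,384,416,430,434,441,446,470,490,516,520,524,552,556,564,570,578,582,584,595,599,603,608,618,634,640,660,664,668,677,678,679,688,696,708,709,710,712,755,818,860 
C1CC2CCC1C2 | 0,1,9,10,143,144,150,151,178,179,283,284,332,333,335,344,582,679,688,708,709,710,839 
C1CC2CCC1CC2 | 0,1,9,10,11,178,179,185,186,192,193,283,284,332,333,335,344,582,679,688,696,708,709,710,776 
c1ccncc1 | 0,9,10,14,178,180,181,255,256,283,284,285,332,344,345,351,355,358,365,370,371,372,373,376,384,387,390,396,403,416,418,434,435,441,442,445,446,447,449,453,464,470,472,482,490,491,495,502,506,516,520,521,523,524,530,538,539,540,545,546,549,552,555,556,564,570,576,577,578,582,584,585,592,595,599,600,603,607,608,613,618,628,633,634,640,656,657,660,664,665,668,677,678,683 
c1ccoc1 | 0,9,10,18,143,146,255,256,283,284,286,332,344,346,352,355,366,370,371,381,384,405,409,416,420,434,436,441,443,446,448,470,476,490,493,498,516,520,524,535,541,542,548,552,553,556,564,565,570,573,574,579,589,594,597,599,604,606,614,619,620,623,626,632,637,641,651,655,666,671,672 
c1cc[nH]c1 | 0,9,10,14,143,145,146,255,256,283,284,285,299,332,344,345,351,355,358,365,370,371,372,373,376,384,387,390,392,393,396,399,400,403,416,418,434,435,441,442,445,446,447,449,453,464,470,472,482,490,491,495,502,506,516,520,521,523,524,527,528,530,538,539,540,545,546,549,552,555,556,564,570,576,577,585,592,599,600,607,613,628,633,643,656,657,665 
C1=CCCCC1 | 0,1,9,10,178,182,283,284,332,344,416,434,441,446,490,516,524,556,582,599,640,660,678,679 
CC(=O)OC1=CC=CC=C1C(=O)O | 0,1,9,10,11,18,19,20,178,179,255,283,284,286,308,332,333,341,344,352,355,356,370,371,374,380,381,382,384,405,406,416,420,430,434,440,441,443,446,452,470,476,490,493,498,516,520,524,535,541,542,548,552,553,556,564,565,570,573,574,575,578,579,581,582,584,589,594,595,597,599,603,604,606,608,614,617,618,619,620,622,623,625,626,632,634,637,639,640,641,642,651,655,660,664,666,667,668,671,672,677,678,679,680,684,688,689,692,698,704,708,709,710,756,819 
CC(C)CC1=CC=C(C=C1)C(C)C(=O)O | 0,1,2,9,10,11,18,19,178,179,255,283,284,286,308,332,333,335,344,352,355,356,370,371,374,380,384,406,416,420,430,434,440,441,443,446,452,470,490,516,520,524,535,552,556,564,570,578,579,582,584,595,597,599,603,608,617,618,634,637,640,641,655,660,664,668,677,678,679,680,684,688,689,692,696,697,698,704,708,709,710,712,713,776 
CN1C=NC2=C1C(=O)N(C(=O)N2C)C | 0,1,9,10,11,14,15,16,18,19,143,145,146,178,180,181,241,243,244,255,256,257,258,259,260,283,284,285,286,332,340,351,352,355,357,358,359,365,373,374,375,376,377,378,379,381,384,386,387,388,389,390,391,396,397,403,416,418,420,431,437,438,439,441,442,443,447,449,450,451,453,464,472,482,484,485,487,491,493,494,495,499,504,506,519,521,523,530,535,536,538,540,545,547,549,553,555,560,569,572,580,585,593,596,601,602,611,613,621,624,628,636,645,646,647,650,654,657,673,674 
C1CCNCC1 | 0,1,9,10,14,178,180,181,283,284,285,299,332,344,345,351,365,390,392,393,528,540,582,592,613,643,656,683 
CCO | 0,9,18,283,284,286,308,344,346,352,366,374,406,571 
CC#N | 9,14,283,284,285,344,351,374,419,429 
C=O | 18,283,286,366,420,448 
OC(=O)C(N)CS | 0,9,14,18,19,33,283,284,285,286,293,299,308,332,338,340,344,345,349,351,352,353,365,368,380,393,406,413,420,440,443,452,528,535,536,566,617,643 
ClC(Cl)Cl | 37,38,283,294,360,361 
CCBr | 0,9,43,283,284,297,327,329,344,374 
O=S(=O)(N)c1ccccc1 | 0,9,10,14,18,19,33,178,179,255,283,284,293,299,305,332,344,353,355,370,371,383,384,414,416,434,441,446,457,459,465,470,483,490,516,520,524,531,532,552,556,564,570,578,582,584,595,599,603,608,618,634,640,660,664,668,677,678,679 
CC(=O)Nc1ccc(O)cc1 | 0,1,9,10,11,14,18,19,178,179,255,283,284,285,286,299,308,332,340,341,344,351,352,355,370,371,374,376,377,381,382,384,390,392,393,406,416,420,434,437,439,441,443,446,449,451,464,470,490,495,498,502,516,520,524,541,542,545,546,548,549,552,556,564,570,573,574,578,582,584,585,590,592,595,599,600,603,606,607,608,613,617,618,619,628,633,634,637,640,641,643,645,651,655,656,657,660,664,665,667,668,677,678,679,680,682,683,689,721,784 
c1ccc(cc1)c1ccccc1 | 0,1,9,10,11,178,179,185,186,255,257,283,284,332,333,344,355,356,370,371,384,416,430,434,441,446,470,490,516,520,524,552,556,564,570,578,582,584,595,599,603,608,618,634,640,660,664,668,677,678,679,688,696,697,708,709,710,712 
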