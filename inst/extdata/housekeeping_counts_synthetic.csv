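gene,E-1,E-2,E-3,E-4,E-5,E-6,E-7,E-8,E-9,E-10,E-13,Es-21,Es-22,Es-23,Es-24,Es-25,Es-26,Es-27,Es-28,Es-29,Es-30,Es-36,Es-37,Es-55,Es-40,Es-41,Es-42,A-50,A-51,A-52,A-53,A-54,A-55,A-56,A-57,A-58,A-59,A-60,A-62,A-63,A-64,A-65,A-66
ACTB,212,330,188,119,369,785,135,140,138,354,1,284,437,183,246,260,473,92,174,184,0,7,0,3,310,280,288,151,247,211,207,128,407,173,117,472,2,3,3,213,50,200,109
GAPDH,327,393,136,179,303,85,205,416,215,227,4,379,204,77,279,220,322,175,192,710,2,9,2,2,321,99,247,129,533,127,125,502,283,335,266,202,3,4,3,312,161,287,301
B2M,203,395,455,511,521,383,780,193,472,238,5,263,216,222,147,245,908,160,192,330,1,0,6,0,253,287,219,95,874,102,264,114,672,146,102,223,2,1,5,219,266,145,107
HPRT1,105,347,125,170,265,78,139,287,283,262,1,112,200,286,115,222,62,491,418,185,3,1,6,7,219,152,242,170,337,98,500,88,67,170,285,407,5,4,1,89,209,216,263
RPL13A,141,297,224,138,186,269,309,263,213,154,0,122,325,331,189,120,91,344,317,282,1,1,4,5,112,427,728,215,31,388,178,82,123,152,386,145,4,3,5,83,222,313,207
YWHAZ,182,103,355,114,197,256,80,384,492,142,0,435,115,363,224,161,164,83,357,240,2,4,2,2,247,298,105,203,138,270,252,336,233,165,355,260,4,8,2,344,331,267,125
SDHA,347,363,290,205,126,185,117,335,500,600,6,202,78,341,121,80,121,276,155,42,3,5,1,1,205,345,375,238,209,95,89,311,632,461,324,411,2,0,6,319,373,104,328
TFRC,176,507,290,299,170,267,149,242,207,249,4,231,93,162,249,50,313,297,301,240,2,0,4,6,233,194,514,400,396,382,506,97,199,116,133,393,2,0,1,159,637,45,184
GUSB,333,335,174,86,217,361,104,342,322,165,10,136,150,252,365,345,295,399,289,97,1,4,1,0,212,344,331,285,114,458,508,202,503,121,392,139,0,2,3,390,292,155,213
HMBS,284,244,145,743,141,100,736,119,312,37,3,321,421,347,248,569,131,594,116,586,1,2,4,3,78,293,461,97,255,248,505,463,558,411,263,220,3,1,5,134,278,254,254
PPIA,536,47,109,181,350,131,120,421,54,83,1,284,483,278,226,190,136,221,426,101,0,1,4,1,242,415,222,143,158,60,257,49,174,173,322,254,0,0,3,151,280,88,587
PGK1,119,121,197,170,255,192,134,286,400,157,5,222,439,348,141,338,346,363,514,54,11,2,0,2,250,290,336,151,50,73,141,68,646,409,69,437,4,1,3,274,214,98,207
POLR2A,386,126,476,230,165,352,240,218,157,100,2,147,166,272,175,158,258,390,174,429,6,0,2,1,422,331,472,187,480,239,222,199,750,180,270,253,3,3,1,153,286,64,150
TBP,414,16,98,393,346,370,177,396,200,96,3,134,290,295,75,88,130,17,224,164,0,0,2,4,90,259,170,428,120,302,238,227,142,213,333,266,6,0,4,161,367,155,319
UBC,400,293,303,160,74,256,456,191,131,42,2,410,288,297,211,193,352,123,234,91,6,5,1,3,175,129,168,307,491,159,93,346,615,96,80,342,1,7,0,159,545,182,304
RPLP0,332,307,316,164,83,251,149,203,266,400,7,260,430,310,178,168,337,152,221,24,0,0,3,1,257,224,177,397,186,102,88,174,289,138,158,167,0,6,1,122,276,437,258
RPL19,107,280,306,136,118,321,191,31,93,381,2,177,131,141,250,90,257,160,139,239,2,6,6,0,404,212,185,291,288,328,302,228,53,237,565,467,1,4,1,59,341,268,162
RPS18,326,106,53,633,277,131,289,80,216,358,2,327,150,193,217,196,234,86,453,634,1,3,2,2,268,340,212,647,307,112,60,373,314,225,154,202,3,5,2,369,224,109,91
EEF1A1,160,128,133,223,544,52,182,82,111,342,3,302,199,90,96,275,100,461,207,392,3,3,0,3,250,390,154,65,244,192,45,143,430,182,67,292,4,0,5,266,275,145,118
PUM1,180,87,452,468,192,213,546,325,376,495,0,111,107,259,117,184,564,309,331,216,0,5,6,6,298,89,225,156,154,81,150,195,175,369,187,369,4,4,3,242,307,302,217
TUBB,228,151,74,277,379,298,221,275,50,171,4,311,583,181,98,235,70,84,222,438,4,5,1,4,321,266,440,129,469,174,655,120,182,188,140,190,5,2,1,647,182,141,301
LDHA,738,256,52,70,313,273,156,171,346,494,2,125,145,254,138,249,354,289,105,205,3,5,3,4,207,151,200,88,152,94,337,177,92,243,233,163,0,0,5,218,239,192,93
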