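# Lebedev-Laikov orbit generators under octahedral symmetry.
# Columns: symmetry class code (1-6), parameters a, b, and the per-point
# weight v (weights normalized so each full grid sums to 1).
# Class codes: 1 = (1,0,0)-type (6 pts), 2 = (1,1,0)/sqrt(2) (12 pts),
# 3 = (1,1,1)/sqrt(3) (8 pts), 4 = (a,a,b) (24 pts), 5 = (a,b,0) (24 pts),
# 6 = (a,b,c) (48 pts).
.lebedev_orbits <- local({
  raw <- c(
    26, 1, 0, 0, 0.047619047619047623,
    26, 2, 0, 0, 0.038095238095238099,
    26, 3, 0, 0, 0.03214285714285714,
    38, 1, 0, 0, 0.0095238095238095247,
    38, 3, 0, 0, 0.03214285714285714,
    38, 5, 0.4597008433809831, 0.88807383397711526, 0.028571428571428571,
    50, 1, 0, 0, 0.0126984126984127,
    50, 2, 0, 0, 0.02257495590828924,
    50, 3, 0, 0, 0.021093750000000001,
    50, 4, 0.30151134457776357, 0.90453403373329089, 0.02017333553791887,
    74, 1, 0, 0, 0.00051306717973384638,
    74, 2, 0, 0, 0.016604069565742039,
    74, 3, 0, 0, -0.029586038961038959,
    74, 4, 0.48038446141526142, 0.73379938570534275, 0.026576207082159461,
    74, 5, 0.3207726489807764, 0.94715622136258792, 0.01652217099371571,
    86, 1, 0, 0, 0.011544011544011539,
    86, 3, 0, 0, 0.011943909085856278,
    86, 4, 0.3696028464541502, 0.85251831170126757, 0.0111105557106034,
    86, 4, 0.69435400660266644, 0.18906355288539498, 0.011876501294537139,
    86, 5, 0.37424303909034118, 0.92733065715117247, 0.011812303746904479,
    110, 1, 0, 0, 0.0038282704949371611,
    110, 3, 0, 0, 0.009793737512487511,
    110, 4, 0.18511563534473621, 0.96512403508659406, 0.0082117372831911097,
    110, 4, 0.69042104838229224, 0.21595729184584844, 0.0099428148911781013,
    110, 4, 0.39568947305594188, 0.82876998125259227, 0.0095954713360709605,
    110, 5, 0.47836902881215021, 0.87815891060406615, 0.0096949963616630268,
    146, 1, 0, 0, 0.00059963136886213809,
    146, 2, 0, 0, 0.0073729997186207557,
    146, 3, 0, 0, 0.0072105153601444878,
    146, 4, 0.67644104001142635, 0.29129888220952682, 0.007116355493117555,
    146, 4, 0.4174961227965453, 0.8070898183595826, 0.0067538294863144768,
    146, 4, 0.1574676672039082, 0.97488864367717321, 0.0075743941590540346,
    146, 6, 0.14035538117131829, 0.4493328323269557, 0.0069910873533032616,
    170, 1, 0, 0, 0.0055448429020373653,
    170, 2, 0, 0, 0.0060713327706707516,
    170, 3, 0, 0, 0.0063836747735150929,
    170, 4, 0.2551252621114134, 0.93264259031269059, 0.0051833875877477908,
    170, 4, 0.67436014603627659, 0.30079359513770149, 0.0063179290098137253,
    170, 4, 0.43189106967194102, 0.79179555939349211, 0.0062016700065890768,
    170, 5, 0.26139313603359882, 0.96523242197644843, 0.0054771433851373477,
    170, 6, 0.1446630744325115, 0.49904531617960368, 0.0059683839876811563,
    194, 1, 0, 0, 0.001782340447244611,
    194, 2, 0, 0, 0.0057169059499771017,
    194, 3, 0, 0, 0.0055733831788487374,
    194, 4, 0.67129734426952259, 0.31419699418258629, 0.0056087040825879972,
    194, 4, 0.2892465627575439, 0.91250909686747372, 0.0051582377118053833,
    194, 4, 0.44469331787174371, 0.77749321931476711, 0.0055187714672736143,
    194, 4, 0.12993354476500671, 0.98297230270725322, 0.0041067770281693937,
    194, 5, 0.34577021976112832, 0.93831921813759156, 0.0050518460646148079,
    194, 6, 0.159041710538353, 0.52511857244364202, 0.0055302489162330944,
    230, 1, 0, 0, -0.055226399197273283,
    230, 3, 0, 0, 0.0044502746074452284,
    230, 4, 0.44920446873976111, 0.77228925314836405, 0.0044968410679214069,
    230, 4, 0.25204194902102012, 0.93431777884581169, 0.0050491534504787522,
    230, 4, 0.69819066584472422, 0.15830220546347831, 0.0039764080180518845,
    230, 4, 0.65874052434609598, 0.36348568495672712, 0.004401400650381017,
    230, 4, 0.040385440500976602, 0.99836768396772746, 0.017245443505444019,
    230, 5, 0.58238423097155845, 0.81291365317336528, 0.0042310830953573454,
    230, 5, 0.3545877390518688, 0.93502274588059298, 0.0051980698640644021,
    230, 6, 0.22721818089981871, 0.48646615358866468, 0.0046957209725688853,
    266, 1, 0, 0, -0.0013137691273269517,
    266, 2, 0, 0, -0.0025227287048593355,
    266, 3, 0, 0, 0.0041868538817005823,
    266, 4, 0.7039373391585475, 0.094575076403713099, 0.0053151679778108843,
    266, 4, 0.1012526248572414, 0.98969480746290539, 0.0040471423770862191,
    266, 4, 0.46474487264205389, 0.75367393925081572, 0.0041124823944069895,
    266, 4, 0.32774206549716289, 0.88609834499749907, 0.0035955848997587816,
    266, 4, 0.66203386636999739, 0.35131512856463343, 0.0042561313514281572,
    266, 5, 0.5257311121191337, 0.85065080835203988, 0.004229582700647239,
    266, 6, 0.1153112011009701, 0.32334845426928988, 0.0040809142257805051,
    266, 6, 0.2314790158712601, 0.5244939240922365, 0.0040714675938309641,
    302, 1, 0, 0, 0.00085459117251281483,
    302, 3, 0, 0, 0.0035991192850255709,
    302, 4, 0.35156403455701052, 0.86764362454408339, 0.003449788424305883,
    302, 4, 0.65663294102196124, 0.37103417838482095, 0.0036048226014198819,
    302, 4, 0.47290541325810048, 0.74345204298755574, 0.003576729661743367,
    302, 4, 0.096183085226147838, 0.9907056213794081, 0.0023521014136891642,
    302, 4, 0.22196452362941779, 0.94945431722644313, 0.0031089531224136749,
    302, 4, 0.70117664160895454, 0.12923867271051442, 0.0036500458076772551,
    302, 5, 0.26441528870606629, 0.96440891487920599, 0.0029823449631718041,
    302, 5, 0.57189558918789607, 0.82032641982775933, 0.0036008209322164601,
    302, 6, 0.25100347517704652, 0.54486773725807736, 0.003571540554273387,
    302, 6, 0.1233548532583327, 0.41277240831685308, 0.0033923122050061698,
    350, 1, 0, 0, 0.0030067967494539364,
    350, 3, 0, 0, 0.0030506277456507714,
    350, 4, 0.70689654639123156, 0.024383301669355525, 0.001621104600288991,
    350, 4, 0.47946826257120251, 0.73499685058774555, 0.0030057014849017524,
    350, 4, 0.19275331548780189, 0.96212905513601443, 0.002990992529653774,
    350, 4, 0.69303579613271227, 0.19850131122336542, 0.0029821706441075955,
    350, 4, 0.36083021155200912, 0.86000181212754701, 0.0027215642373109926,
    350, 4, 0.64984861614961686, 0.39419988860583888, 0.0030335137958111421,
    350, 5, 0.19329450132303391, 0.98114078284325723, 0.0030079495552185328,
    350, 5, 0.38004949198993032, 0.92496615269867899, 0.0028819646030553074,
    350, 6, 0.28995588254995741, 0.53512304771827623, 0.0029583576265356966,
    350, 6, 0.09684121455103957, 0.55218207434939925, 0.0030360200264070883,
    350, 6, 0.1833434647041659, 0.37800918987448673, 0.0028321874039263033,
    434, 1, 0, 0, 0.00052658979682244358,
    434, 2, 0, 0, 0.0025482199720026069,
    434, 3, 0, 0, 0.0025123174189273069,
    434, 4, 0.69093463075091111, 0.21264682470755186, 0.0025304038011863552,
    434, 4, 0.17748360546091579, 0.96798715879147279, 0.0020142790209185281,
    434, 4, 0.4914342637784746, 0.71901650104084347, 0.0025017251684029355,
    434, 4, 0.64566647074242556, 0.40771266489776975, 0.0025132671745975639,
    434, 4, 0.28612890103076383, 0.91447280112087248, 0.0023026947822274162,
    434, 4, 0.075680843671780185, 0.99425591263127788, 0.001462495621594614,
    434, 4, 0.39272597633680018, 0.83158440041923232, 0.0024453734373129799,
    434, 5, 0.47159869115131597, 0.8818132877794288, 0.002417442375638981,
    434, 5, 0.2102725228573068, 0.9776428111182649, 0.0019109512821795321,
    434, 6, 0.20548236964030439, 0.4502330382582625, 0.002416930044324775,
    434, 6, 0.10680182607580488, 0.59051570489252714, 0.0025122368545634952,
    434, 6, 0.31042840351665446, 0.55501523610768067, 0.0024966440545530861,
    434, 6, 0.099217696364292479, 0.33443631453434552, 0.0022366077604378488,
    590, 1, 0, 0, 0.00030951212953061878,
    590, 3, 0, 0, 0.0018523796985974892,
    590, 4, 0.70409549382274694, 0.092190407076898254, 0.0018717906392777444,
    590, 4, 0.68077440664552435, 0.2703560883591648, 0.0018588125854383172,
    590, 4, 0.63725469392587519, 0.43337386877715439, 0.0018520288282962134,
    590, 4, 0.50444197078003583, 0.70076857537357296, 0.0018467159561512425,
    590, 4, 0.42157617840109668, 0.80283687733527376, 0.0018184717781627691,
    590, 4, 0.3317920736472123, 0.88307872793413256, 0.0017495646572811543,
    590, 4, 0.2384736701421887, 0.94141415822040253, 0.0016172106472544113,
    590, 4, 0.14590364491577629, 0.97848058376269387, 0.0013847372348516919,
    590, 4, 0.06095034115507196, 0.99627812975401642, 0.00097643311650510523,
    590, 5, 0.61168434420098761, 0.79110192962690196, 0.0018571611967740781,
    590, 5, 0.39647553481998582, 0.91804528771145399, 0.0017051539963958645,
    590, 5, 0.17247820099077241, 0.98501333502800192, 0.0013003216858860482,
    590, 6, 0.35182809277335192, 0.56102638086220602, 0.0018428664729052862,
    590, 6, 0.26347166559379498, 0.47423928425519801, 0.0018026589343774512,
    590, 6, 0.18166408403602091, 0.59841264978853803, 0.0018498305604436602,
    590, 6, 0.17207952256568779, 0.37910354076955632, 0.0017139045071067093,
    590, 6, 0.082130215819325114, 0.27786731905862438, 0.0015552136033968082,
    590, 6, 0.089992058420748755, 0.50335642710751172, 0.0018022391280085252,
    770, 1, 0, 0, 0.0002192942088181184,
    770, 2, 0, 0, 0.0014364336173190799,
    770, 3, 0, 0, 0.0014219403443358771,
    770, 4, 0.050872044105023599, 0.99740867765282304, 0.00067981235110505011,
    770, 4, 0.1228198790178831, 0.98479975357230121, 0.00099131842352949114,
    770, 4, 0.2026890814408786, 0.95803667598339137, 0.0011802078332389489,
    770, 4, 0.28477451564642942, 0.91531795048315479, 0.001296599602080921,
    770, 4, 0.36567190789780257, 0.8559019286978865, 0.0013658714274283161,
    770, 4, 0.44282648867134689, 0.77962131952763514, 0.0014029886047753251,
    770, 4, 0.51406196272497351, 0.6866444472641543, 0.001418645563595609,
    770, 4, 0.63064012191668029, 0.45231192031365841, 0.0014213767418516619,
    770, 4, 0.67168833320226118, 0.31252130500165326, 0.0014239964754909622,
    770, 4, 0.69797926853368808, 0.16015580349882902, 0.0014315540421785671,
    770, 5, 0.1446865674195309, 0.98947753749559852, 0.00092544014998653678,
    770, 5, 0.3390263475411216, 0.94077687879375871, 0.001250239995053509,
    770, 5, 0.5335804651263506, 0.84574930519365332, 0.0013943658433292301,
    770, 6, 0.069440243933494128, 0.2355187894242326, 0.0011270890946717489,
    770, 6, 0.226900410952946, 0.41021824740457302, 0.0013457537609106701,
    770, 6, 0.08025574607775339, 0.62143024174816053, 0.0014249572833167829,
    770, 6, 0.14679995278965721, 0.32452843457173941, 0.0012615233412377499,
    770, 6, 0.15715077698247271, 0.52244821896966298, 0.001392547106052696,
    770, 6, 0.2365702993157246, 0.60175466340895578, 0.0014187616778776561,
    770, 6, 0.077148158667657327, 0.43465755161411629, 0.0013383666844795539,
    770, 6, 0.30629366662107299, 0.49088265890376159, 0.0013937008626761309,
    770, 6, 0.38224773795247868, 0.56487681490995001, 0.0014159147574669317,
    974, 1, 0, 0, 0.00014382941905274308,
    974, 3, 0, 0, 0.0011257722882870038,
    974, 4, 0.042929635453413467, 0.99815534502384651, 0.00049480293419492402,
    974, 4, 0.1051426854086404, 0.98888322435468556, 0.00073579901091254678,
    974, 4, 0.1750024867623087, 0.96889022043470741, 0.00088891327713043825,
    974, 4, 0.2477653379650257, 0.93660273040716313, 0.00098883478389214332,
    974, 4, 0.32065671239559568, 0.89126794264760612, 0.0010532996817094707,
    974, 4, 0.39165207498499832, 0.83259672370235194, 0.001092778807014578,
    974, 4, 0.4590825874187624, 0.76058290531525141, 0.0011143893940632268,
    974, 4, 0.52145638884158607, 0.6754009691084143, 0.0011237247880515548,
    974, 4, 0.62531702446541992, 0.46685890569574318, 0.0011252393252438138,
    974, 4, 0.66379267445231704, 0.34461365423743795, 0.0011261532718159048,
    974, 4, 0.69104103984983012, 0.21195415185018429, 0.0011302869311238409,
    974, 4, 0.70529070074577604, 0.071624401449955549, 0.0011349865343639547,
    974, 5, 0.123668676265799, 0.99232356543149014, 0.00068233679271099295,
    974, 5, 0.2940777114468387, 0.95578151249654841, 0.00094541581604470947,
    974, 5, 0.46977538492076493, 0.88278598070118164, 0.0010744299753856787,
    974, 5, 0.63345632411395669, 0.77377844725737477, 0.0011293000865691318,
    974, 6, 0.059740486141813418, 0.20291287527775231, 0.00084368845009019514,
    974, 6, 0.13757604084736361, 0.46026219424840542, 0.0010752557204488848,
    974, 6, 0.33910165263362863, 0.50306739996620364, 0.0011085772368644618,
    974, 6, 0.127167519143982, 0.28176064224421338, 0.00095664753237833557,
    974, 6, 0.26931207404135121, 0.43315612917201568, 0.0010806632507173908,
    974, 6, 0.1419786452601918, 0.62561673585808142, 0.0011267971311962948,
    974, 6, 0.067092846007382551, 0.37983952168591573, 0.0010225687153580607,
    974, 6, 0.070577381832561722, 0.55175054214235197, 0.0011089602677131077,
    974, 6, 0.27838884778821549, 0.60296191561591872, 0.0011227906534357658,
    974, 6, 0.1979578938917407, 0.35896063295890962, 0.0010324018471174598,
    974, 6, 0.2087307061103274, 0.53486664381354765, 0.0011072493822838537,
    974, 6, 0.40551221378728358, 0.56749975460743729, 0.0011217800485199719,
    1202, 1, 0, 0, 0.0001105189233267572,
    1202, 2, 0, 0, 0.00092052327380907396,
    1202, 3, 0, 0, 0.00091331597864435625,
    1202, 4, 0.037126364496570891, 0.99862068179991925, 0.00036904218980178988,
    1202, 4, 0.091400604122622228, 0.99161073972201386, 0.00056039909286806605,
    1202, 4, 0.15310778524699059, 0.97627660639468505, 0.00068652976292826089,
    1202, 4, 0.2180928891660612, 0.95124706748057852, 0.00077203385511456313,
    1202, 4, 0.28398745322001751, 0.91580688620866835, 0.00083015459588947952,
    1202, 4, 0.34911776009637641, 0.86961691518195405, 0.00086866925501796267,
    1202, 4, 0.41214314614443093, 0.81257372229991565, 0.00089270762858468904,
    1202, 4, 0.47189936271491267, 0.74472946963210651, 0.00090608202385682179,
    1202, 4, 0.52731454528423372, 0.66624225373610435, 0.00091197772549408669,
    1202, 4, 0.62094753324440188, 0.47838093807695226, 0.00091287201386041814,
    1202, 4, 0.6569722711857291, 0.36983086645942581, 0.00091307149356917349,
    1202, 4, 0.68417883090701426, 0.25258395570071829, 0.00091528737845541163,
    1202, 4, 0.70126043301236307, 0.12832618665972312, 0.00091874362743216544,
    1202, 5, 0.10723822154781661, 0.99423335482132236, 0.00051769773129656943,
    1202, 5, 0.25820689594969681, 0.96608964329611902, 0.00073311436821014173,
    1202, 5, 0.41727529553067172, 0.90878013168191052, 0.00084632328363799282,
    1202, 5, 0.57003669117925027, 0.82161923706143347, 0.00090311226942539917,
    1202, 6, 0.052106394770112544, 0.1771774022615325, 0.00064857784531632573,
    1202, 6, 0.11156409571564851, 0.24757164634262879, 0.00074350309109823688,
    1202, 6, 0.05905888853235372, 0.33546162890664888, 0.00079985278918390538,
    1202, 6, 0.17465516775786288, 0.31736152466119771, 0.00081017314974680184,
    1202, 6, 0.1217235051095989, 0.40902684270853568, 0.00084833895745943305,
    1202, 6, 0.23902784793817244, 0.3854291150669224, 0.00085562992573118117,
    1202, 6, 0.062662506241541988, 0.49322211848512848, 0.00088032086797382593,
    1202, 6, 0.18575051945473373, 0.47853206759224348, 0.00088110481824257196,
    1202, 6, 0.30294669735289831, 0.45074225931570638, 0.00088502823412654438,
    1202, 6, 0.12677748006842818, 0.56321230207620998, 0.00090213422990406526,
    1202, 6, 0.24941121623622375, 0.54343035696939002, 0.0009010091677105086,
    1202, 6, 0.36498322605976541, 0.51235184864198713, 0.00090226929384269153,
    1202, 6, 0.064245492242207852, 0.63942796347491015, 0.00091580161746934654,
    1202, 6, 0.19060182227792313, 0.6269805509024392, 0.00091315780031894355,
    1202, 6, 0.31122759471496081, 0.60311616930963097, 0.00091078135794827046,
    1202, 6, 0.42386447815223383, 0.56937024984684415, 0.00091057602589701258,
    1454, 1, 0, 0, 7.7771607432612467e-05,
    1454, 3, 0, 0, 0.00075576464130047011,
    1454, 4, 0.032292906634138543, 0.99895662386423845, 0.00028416338060906172,
    1454, 4, 0.080367332714622222, 0.99352009726259405, 0.00043744191270535552,
    1454, 4, 0.1354289960531653, 0.98148763316511711, 0.00054171747408721723,
    1454, 4, 0.19389638611144261, 0.96166958094027533, 0.00061480008913585927,
    1454, 4, 0.25373437150112749, 0.9334011664005224, 0.00066643944858007045,
    1454, 4, 0.31352514347525701, 0.89632804754600814, 0.00070250393569232196,
    1454, 4, 0.37215583393753382, 0.85029410825461882, 0.00072685117892496267,
    1454, 4, 0.42868095751956958, 0.79527685325313602, 0.00074226375342086287,
    1454, 4, 0.48225101282829941, 0.7313466491699806, 0.00075095450358412142,
    1454, 4, 0.53206793335662628, 0.65864059136012676, 0.00075485350577184009,
    1454, 4, 0.61729981953942736, 0.48773134571522136, 0.00075540889697740018,
    1454, 4, 0.65106798491274809, 0.39015504359588543, 0.00075531471744428084,
    1454, 4, 0.67773152516873603, 0.28523667293130073, 0.00075647676532922964,
    1454, 4, 0.69631094106487412, 0.17407511799995667, 0.00075879918085187297,
    1454, 4, 0.70589350098317494, 0.058555363028785182, 0.00076082618320330283,
    1454, 5, 0.094185985013862425, 0.99555461940918566, 0.00040216804478749164,
    1454, 5, 0.22906303958598634, 0.97341159017942092, 0.00058048717939459637,
    1454, 5, 0.37365098398005542, 0.92756937323886257, 0.00067921519559451589,
    1454, 5, 0.51564514700014707, 0.8568022422795103, 0.00073367412112862939,
    1454, 5, 0.64716547762083976, 0.76234955537193716, 0.00075818663009896085,
    1454, 6, 0.43870280398895012, 0.5707522908892223, 0.00075382578598007428,
    1454, 6, 0.38589084147626168, 0.51964633884030831, 0.00074835172470531233,
    1454, 6, 0.33019373723438539, 0.4646337531215351, 0.00073717636611120589,
    1454, 6, 0.27254235735637772, 0.40639016975576908, 0.00071834488957569337,
    1454, 6, 0.21395102374952499, 0.34563294666430872, 0.00068958155298221913,
    1454, 6, 0.1555922309786647, 0.28313951210503319, 0.00064801058017928859,
    1454, 6, 0.098928789796860969, 0.21976820229253299, 0.00058975588965946358,
    1454, 6, 0.0459864291067551, 0.1564696098650355, 0.00050957088492473461,
    1454, 6, 0.3376625140173426, 0.60273566737212947, 0.00075369064289097548,
    1454, 6, 0.28223013097279881, 0.54960323202550965, 0.00074725059655751181,
    1454, 6, 0.224863234259254, 0.49217077552345673, 0.00073430171322796977,
    1454, 6, 0.16662247234564789, 0.43094229985984828, 0.00071308715821774451,
    1454, 6, 0.1086964901822169, 0.36641081823136717, 0.00068170220321127763,
    1454, 6, 0.052519897841200848, 0.29901890577584361, 0.00063809411456041212,
    1454, 6, 0.2297523657550023, 0.62687240131449984, 0.00075503813779203102,
    1454, 6, 0.17230806070938001, 0.57073241448346068, 0.00074786466401448022,
    1454, 6, 0.1140238465390513, 0.50963609019603651, 0.00073359187206012205,
    1454, 6, 0.056115220958825367, 0.44387299383124562, 0.00071101205276581192,
    1454, 6, 0.11641744231408729, 0.64199784710823893, 0.00075713639786895008,
    1454, 6, 0.057975895314452193, 0.58172180618026115, 0.00074899083290792345,
    2030, 1, 0, 0, 4.6560318991974309e-05,
    2030, 3, 0, 0, 0.00054215491952955069,
    2030, 4, 0.025408353368143479, 0.99935420705485556, 0.0001778522133346553,
    2030, 4, 0.063993228005049155, 0.99589644719668902, 0.00028113254056827961,
    2030, 4, 0.1088269469804125, 0.9880857205839203, 0.00035488963126314592,
    2030, 4, 0.15706707988182869, 0.97501787923852479, 0.00040903108971733639,
    2030, 4, 0.2071163932282514, 0.95614099342735048, 0.00044932861341699654,
    2030, 4, 0.2578914044450844, 0.93111978124550865, 0.00047937284479627232,
    2030, 4, 0.3085687558169623, 0.89976143830859068, 0.00050154153191642647,
    2030, 4, 0.35847197062670239, 0.86197197898192557, 0.00051751273726779372,
    2030, 4, 0.40701355944287088, 0.8177285153761541, 0.0005285522262081019,
    2030, 4, 0.45366186262226382, 0.76706051182693302, 0.00053568327037139618,
    2030, 4, 0.49791956864635772, 0.71003676406088312, 0.00053979147361751703,
    2030, 4, 0.53930751111269992, 0.64675715451384852, 0.00054168994415999296,
    2030, 4, 0.61156176768439163, 0.50198048628754921, 0.0005419308476889938,
    2030, 4, 0.64143084351601587, 0.42087165023634548, 0.00054169369020305963,
    2030, 4, 0.66640994127216069, 0.33435846085791021, 0.00054195443387031639,
    2030, 4, 0.68591617712149133, 0.24297735681762167, 0.00054289836566309745,
    2030, 4, 0.69936255935038905, 0.14759410949542376, 0.00054422865000981931,
    2030, 4, 0.70623933877193801, 0.049517600325051238, 0.00054522503450573007,
    2030, 5, 0.074790281683497634, 0.99719928488026055, 0.00025680024977285302,
    2030, 5, 0.18489511539693659, 0.98275825934069538, 0.00038272117002921449,
    2030, 5, 0.30595290665813052, 0.95204664744299228, 0.00045794915619178241,
    2030, 5, 0.42855561010213622, 0.90351540609443171, 0.00050420039690835742,
    2030, 5, 0.5468758653496526, 0.83721370503478298, 0.00053127088899760245,
    2030, 5, 0.65658219783434391, 0.75425447793634115, 0.00054384017907471174,
    2030, 6, 0.036819172264396412, 0.12539015723671171, 0.00033160418731973442,
    2030, 6, 0.079824876072133011, 0.1775721510383941, 0.00038991135671537713,
    2030, 6, 0.1264640966592335, 0.2305693358216114, 0.00043433433272013089,
    2030, 6, 0.17515856834189569, 0.28365028459920633, 0.00046794152623189192,
    2030, 6, 0.224799590763267, 0.33617947462325898, 0.00049308479816310307,
    2030, 6, 0.27452992574222462, 0.3875979172264824, 0.00051150318675400913,
    2030, 6, 0.32363734824411178, 0.43740193169990738, 0.00052452171484573666,
    2030, 6, 0.37149678594367408, 0.48512758433400222, 0.00053320414998953209,
    2030, 6, 0.4175353646321745, 0.53033918038068684, 0.00053845831260215425,
    2030, 6, 0.46120844063554611, 0.57261973805962874, 0.00054110672107988522,
    2030, 6, 0.04258040133043952, 0.2431520732564863, 0.00042597973914687142,
    2030, 6, 0.088694243067227216, 0.30020968008958693, 0.00046049313684600211,
    2030, 6, 0.1368811706510655, 0.35585544574574318, 0.00048718148782552021,
    2030, 6, 0.1860739985015033, 0.40977825370488868, 0.00050722429100748853,
    2030, 6, 0.23542350773958531, 0.46163376660674582, 0.000521706984523535,
    2030, 6, 0.28420749213470109, 0.51107070084178741, 0.00053157859662803105,
    2030, 6, 0.33177844149841018, 0.55774152861637949, 0.0005376833708758905,
    2030, 6, 0.37752990020407001, 0.601306043136695, 0.00054080320920695207,
    2030, 6, 0.045993678871645918, 0.36615967672617811, 0.00048427449179048662,
    2030, 6, 0.094048937736544214, 0.42376331535065809, 0.00050489260761881296,
    2030, 6, 0.14313771090919711, 0.47863284546584522, 0.00052026079804783727,
    2030, 6, 0.19241863888435701, 0.53057020767897745, 0.00053099323883257427,
    2030, 6, 0.24115909447751899, 0.57934362242317883, 0.00053774197708952084,
    2030, 6, 0.28868714915836052, 0.62470690170947474, 0.00054116963316777167,
    2030, 6, 0.048049787749532058, 0.48743155525352039, 0.00051979962932824201,
    2030, 6, 0.097168571993666644, 0.54273373220590526, 0.00053111208366229447,
    2030, 6, 0.14652058397950549, 0.59434937472466998, 0.00053843093199569514,
    2030, 6, 0.19535794498035741, 0.64213140335649432, 0.00054218595040518862,
    2030, 6, 0.04916375015738108, 0.60206283747139799, 0.00053909483550463135,
    2030, 6, 0.098616215401270052, 0.65292225298568807, 0.00054333127050278454)
  m <- matrix(raw, ncol = 5, byrow = TRUE)
  colnames(m) <- c("order", "code", "a", "b", "v")
  m
})

.lebedev_supported <- sort(unique(.lebedev_orbits[, "order"]))
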