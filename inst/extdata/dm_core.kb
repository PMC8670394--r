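# Data-mining core knowledge base: CRISP-DM stages and processes,
# algorithms with their characteristics, inputs and parameters.
# One axiom per line, tab-separated; see ?read_kb for the format.

# --- top-level taxonomy ---
SUBCLASSOF	Stage	Process
SUBCLASSOF	BusinessUnderstanding	Stage
SUBCLASSOF	DataUnderstanding	Stage
SUBCLASSOF	DataPreparation	Stage
SUBCLASSOF	Modelling	Stage
SUBCLASSOF	Evaluation	Stage
SUBCLASSOF	Deployment	Stage

# --- stage sequencing (hasPostprocess chain with inverses) ---
RESTRICTION	BusinessUnderstanding	hasPostprocess	some	DataUnderstanding
RESTRICTION	DataUnderstanding	hasPostprocess	some	DataPreparation
RESTRICTION	DataPreparation	hasPostprocess	some	Modelling
RESTRICTION	Modelling	hasPostprocess	some	Evaluation
RESTRICTION	Evaluation	hasPostprocess	some	Deployment
RESTRICTION	DataUnderstanding	postprocessOf	some	BusinessUnderstanding
RESTRICTION	DataPreparation	postprocessOf	some	DataUnderstanding
RESTRICTION	Modelling	postprocessOf	some	DataPreparation
RESTRICTION	Evaluation	postprocessOf	some	Modelling
RESTRICTION	Deployment	postprocessOf	some	Evaluation

# --- sub-processes ---
SUBCLASSOF	application_objectives_identification	Process
SUBCLASSOF	application_resources_assessment	Process
SUBCLASSOF	data_mining_goals_identification	Process
RESTRICTION	application_objectives_identification	subprocessOf	some	BusinessUnderstanding
RESTRICTION	application_resources_assessment	subprocessOf	some	BusinessUnderstanding
RESTRICTION	data_mining_goals_identification	subprocessOf	some	BusinessUnderstanding
SUBCLASSOF	DataDescription	Process
SUBCLASSOF	DataQualityVerification	Process
RESTRICTION	DataDescription	subprocessOf	some	DataUnderstanding
RESTRICTION	DataQualityVerification	subprocessOf	some	DataUnderstanding
SUBCLASSOF	MissingValueProcessing	Process
SUBCLASSOF	DimensionReduction	Process
RESTRICTION	MissingValueProcessing	subprocessOf	some	DataPreparation
RESTRICTION	DimensionReduction	subprocessOf	some	DataPreparation
SUBCLASSOF	ConsistencyModelling	Modelling
SUBCLASSOF	ResultSummary	Process
RESTRICTION	ResultSummary	subprocessOf	some	Evaluation

# --- process inputs and outputs ---
RESTRICTION	MissingValueProcessing	hasInput	some	DataWithMissingValue
RESTRICTION	MissingValueProcessing	hasOutput	some	DataWithoutMissingValue
RESTRICTION	Modelling	hasInput	some	DataWithoutMissingValue
RESTRICTION	Modelling	hasOutput	some	OutputModel
RESTRICTION	DimensionReduction	hasInput	some	HighDimensionalData
RESTRICTION	DimensionReduction	hasOutput	some	LowDimensionalData

# --- outputs of business-understanding sub-processes ---
SUBCLASSOF	data_mining_goals_description	Output
SUBCLASSOF	data_mining_success_criteria_description	Output
RESTRICTION	data_mining_goals_description	outputOf	some	data_mining_goals_identification
RESTRICTION	data_mining_success_criteria_description	outputOf	some	data_mining_goals_identification

# --- INPUT sub-ontology: data characteristics and task requirements ---
SUBCLASSOF	DataCharacteristic	INPUT
SUBCLASSOF	DataAnalysisTask	INPUT
SUBCLASSOF	Continuous	DataCharacteristic
SUBCLASSOF	Missing_Random	DataCharacteristic
SUBCLASSOF	Missing_not_Random	DataCharacteristic
SUBCLASSOF	DataWithMissingValue	DataCharacteristic
SUBCLASSOF	DataWithoutMissingValue	DataCharacteristic
SUBCLASSOF	DataWithClassImbalance	DataCharacteristic
SUBCLASSOF	SmallSizeDataset	DataCharacteristic
SUBCLASSOF	LongTSDataset	DataCharacteristic
SUBCLASSOF	HighDimensionalData	DataCharacteristic
SUBCLASSOF	LowDimensionalData	DataCharacteristic
SUBCLASSOF	BinaryClassification	DataAnalysisTask
DATAPROP	LongTSDataset	hasMinLength	700	integer

# --- output models ---
SUBCLASSOF	BinaryClassificationModel	OutputModel
RESTRICTION	BinaryClassificationModel	availableFor	some	BinaryClassification

# --- algorithm characteristics ---
SUBCLASSOF	ToleranceToClassImbalance	Characteristics
SUBCLASSOF	HandlingOfClassificationCosts	Characteristics
SUBCLASSOF	BiasVarianceProfile	Characteristics
RESTRICTION	ToleranceToClassImbalance	suitableFor	some	DataWithClassImbalance
RESTRICTION	ToleranceToClassImbalance	characteristicOf	some	BayesianAlgorithm
RESTRICTION	HandlingOfClassificationCosts	characteristicOf	some	BayesianAlgorithm
RESTRICTION	BiasVarianceProfile	characteristicOf	some	BayesianAlgorithm

# --- algorithm taxonomy ---
SUBCLASSOF	classificationModelingAlgorithms	Algorithm
SUBCLASSOF	ClusteringModelingAlgorithm	Algorithm
SUBCLASSOF	DescriptiveModelingAlgorithm	Algorithm
SUBCLASSOF	ImputationAlgorithm	Algorithm
SUBCLASSOF	DimensionReductionAlgorithm	Algorithm
SUBCLASSOF	BayesianAlgorithm	classificationModelingAlgorithms
SUBCLASSOF	SVC-Algorithm	classificationModelingAlgorithms
SUBCLASSOF	KNN_Algorithm	Algorithm
SUBCLASSOF	PCA	DimensionReductionAlgorithm
RESTRICTION	PCA	employedBy	some	DimensionReduction

# --- algorithm parameters ---
SUBCLASSOF	CapacityParameter	Parameter
SUBCLASSOF	KernelTypeParameter	Parameter
SUBCLASSOF	NeighborCountParameter	Parameter
SUBCLASSOF	DistanceMeasureParameter	Parameter
RESTRICTION	CapacityParameter	parameterOf	some	SVC-Algorithm
RESTRICTION	KernelTypeParameter	parameterOf	some	SVC-Algorithm
RESTRICTION	NeighborCountParameter	parameterOf	some	KNN_Imputation_ED
RESTRICTION	DistanceMeasureParameter	parameterOf	some	KNN_Imputation_ED

# --- imputation algorithms ---
SUBCLASSOF	KNN_Imputation_ED	ImputationAlgorithm
SUBCLASSOF	Mean_Imputation	ImputationAlgorithm
RESTRICTION	KNN_Imputation_ED	employedBy	some	MissingValueProcessing
RESTRICTION	KNN_Imputation_ED	suitableFor	some	Continuous
RESTRICTION	KNN_Imputation_ED	suitableFor	some	Missing_not_Random
RESTRICTION	KNN_Imputation_ED	employs	some	KNN_Algorithm
RESTRICTION	KNN_Imputation_ED	hasMeasure	some	Euclidean_Distance
RESTRICTION	Mean_Imputation	employedBy	some	MissingValueProcessing
RESTRICTION	Mean_Imputation	suitableFor	some	Continuous
RESTRICTION	Mean_Imputation	suitableFor	some	Missing_Random
SUBCLASSOF	DistanceMeasure	Measure
SUBCLASSOF	Euclidean_Distance	DistanceMeasure

# --- descriptive algorithms for consistency analysis ---
SUBCLASSOF	CF	DescriptiveModelingAlgorithm
SUBCLASSOF	Kupershtokh_Mirkin_Trofimov	DescriptiveModelingAlgorithm
RESTRICTION	CF	employedBy	some	ConsistencyModelling
RESTRICTION	CF	suitableFor	some	ConsistencyAnalysis
RESTRICTION	CF	suitableFor	some	Continuous
RESTRICTION	Kupershtokh_Mirkin_Trofimov	employedBy	some	ConsistencyModelling
RESTRICTION	Kupershtokh_Mirkin_Trofimov	suitableFor	some	ConsistencyAnalysis
RESTRICTION	Kupershtokh_Mirkin_Trofimov	suitableFor	some	Continuous

# --- characteristic dependencies: a missingness mechanism characterizes
# --- data with missing values and lapses once those are resolved
RESTRICTION	Missing_not_Random	characterizes	some	DataWithMissingValue
RESTRICTION	Missing_Random	characterizes	some	DataWithMissingValue
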